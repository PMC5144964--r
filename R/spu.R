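#' Power set for the adaptive SPU tests
#'
#' Validates and orders the candidate exponents gamma.  `Inf` selects
#' the max-component statistic `max_j |U_j|`.  The default
#' `c(1:8, Inf)` is the simulation-study choice; gene-scan analyses of
#' sets dominated by singletons typically drop `Inf` and use `1:6` for
#' numerical stability.
#'
#' @param gammas numeric vector of positive integers, optionally with
#'   one `Inf`.
#' @return validated numeric vector of class `gamma_set`.
#' @export
gamma_set <- function(gammas = c(1:8, Inf)) {
  gammas <- as.numeric(gammas)
  if (!length(gammas)) stop("gamma set must be non-empty")
  if (anyDuplicated(gammas)) stop("duplicate gamma values")
  fin <- gammas[is.finite(gammas)]
  if (any(fin < 1) || any(fin != round(fin)))
    stop("finite gamma values must be positive integers")
  structure(sort(gammas), class = "gamma_set")
}

#' Sum of powered score statistic
#'
#' `T_SPU(gamma) = sum_j U_j^gamma` for finite gamma and
#' `max_j |U_j|` for `gamma = Inf`.  Growing gamma concentrates weight
#' on the largest score components (effectively selecting variants);
#' even gamma ignores effect direction, odd gamma rewards a shared
#' direction.
#'
#' @param u score vector.
#' @param gamma positive integer or `Inf`.
#' @return scalar statistic.
#' @examples
#' spu_statistic(c(1, -2, 3), 2)    # 14
#' spu_statistic(c(1, -2, 3), Inf)  # 3
#' @export
spu_statistic <- function(u, gamma) {
  if (is.infinite(gamma)) max(abs(u)) else sum(u^gamma)
}

# B x G matrix of SPU statistics from a B x k null score matrix
spu_stat_matrix <- function(u_null, gammas) {
  B <- nrow(u_null)
  out <- matrix(NA_real_, B, length(gammas))
  pw <- matrix(1, B, ncol(u_null))
  last <- 0
  for (g in seq_along(gammas)) {
    gam <- gammas[g]
    if (is.infinite(gam)) {
      out[, g] <- apply(abs(u_null), 1, max)
    } else {
      while (last < gam) { pw <- pw * u_null; last <- last + 1 }
      out[, g] <- rowSums(pw)
    }
  }
  out
}

#' Resampling p-value for a single statistic
#'
#' `p = [sum_b I(|T^(b)| >= |T|) + 1] / (B + 1)`; ties count toward the
#' null, so the attainable minimum is `1/(B+1)`.  With
#' `two_sided_abs = FALSE` the raw values are compared (for statistics
#' that are nonnegative by construction the two give identical results).
#'
#' @param t_obs observed statistic.
#' @param t_null vector of B null statistics.
#' @param two_sided_abs compare absolute values (default).
#' @return p-value in `(0, 1]`.
#' @export
resampling_pvalue <- function(t_obs, t_null, two_sided_abs = TRUE) {
  B <- length(t_null)
  stopifnot(B >= 1)
  if (two_sided_abs) (sum(abs(t_null) >= abs(t_obs)) + 1) / (B + 1)
  else (sum(t_null >= t_obs) + 1) / (B + 1)
}

#' SPU(gamma) p-values from shared resamples
#'
#' Computes the p-value of every SPU(gamma) statistic from the same
#' resampled null score matrix.  Because the p-values depend only on the
#' ranks of the statistics, they are invariant to monotone transforms
#' such as `(.)^(1/gamma)`.
#'
#' @param sr a [resample_null_scores()] result.
#' @param gammas a [gamma_set()] (or vector accepted by it).
#' @return named numeric vector of p-values, one per gamma.
#' @export
spu_test <- function(sr, gammas = gamma_set()) {
  gammas <- gamma_set(gammas)
  t_obs <- vapply(gammas, function(g) spu_statistic(sr$u_obs, g), 0)
  t_null <- spu_stat_matrix(sr$u_null, gammas)
  B <- sr$b_used
  p <- (colSums(abs(t_null) >= rep(abs(t_obs), each = B)) + 1) / (B + 1)
  names(p) <- paste0("spu", ifelse(is.finite(gammas), gammas, "inf"))
  p
}

aspu_machinery <- function(sr, gammas) {
  gammas <- gamma_set(gammas)
  if (sr$b_used < 2) stop("aSPU needs at least B = 2 resamples")
  B <- sr$b_used
  t_obs <- vapply(gammas, function(g) spu_statistic(sr$u_obs, g), 0)
  t_null <- abs(spu_stat_matrix(sr$u_null, gammas))
  p_gamma <- (colSums(t_null >= rep(abs(t_obs), each = B)) + 1) / (B + 1)
  # leave-one-out null p-values over the shared resamples:
  # p_gamma^(b) = [#{b1 != b : T^(b1) >= T^(b)} + 1] / B
  #             = (B + 1 - min-rank(T^(b))) / B
  p_null <- matrix(NA_real_, B, length(gammas))
  for (g in seq_along(gammas))
    p_null[, g] <- (B + 1 - rank(t_null[, g], ties.method = "min")) / B
  minp_null <- do.call(pmin, as.data.frame(p_null))
  minp_obs <- min(p_gamma)
  aspu_p <- (sum(minp_null <= minp_obs) + 1) / (B + 1)
  names(p_gamma) <- paste0("spu", ifelse(is.finite(gammas), gammas, "inf"))
  list(p = aspu_p, spu = p_gamma)
}

#' Adaptive SPU test
#'
#' Takes `T_aSPU = min_gamma P_SPU(gamma)` and calibrates it against the
#' minimum over the same gamma set of leave-one-out null p-values
#' computed on the shared resample matrix (no nested resampling):
#' `P_aSPU = [sum_b I(T_aSPU^(b) <= T_aSPU) + 1] / (B + 1)`.
#'
#' @inheritParams spu_test
#' @return list with elements `p` (the aSPU p-value) and `spu`
#'   (named per-gamma SPU p-values).
#' @export
aspu_test <- function(sr, gammas = gamma_set()) {
  if (isTRUE(sr$robust))
    stop("aspu_test expects a Gaussian score_result; use aspur_test")
  aspu_machinery(sr, gammas)
}

#' Adaptive robust SPU test
#'
#' The aSPU combination applied to Huber-score statistics
#' `T_SPUr(gamma) = sum_j U_H,j^gamma`: identical resampling and min-p
#' machinery, but every score (observed and resampled) is the bounded
#' Huber score, so single outlying trait values cannot dominate.
#'
#' @param sr_robust a [resample_null_scores()] result built with
#'   `robust = TRUE`.
#' @inheritParams spu_test
#' @return list with elements `p` (the aSPUr p-value) and `spu`
#'   (named per-gamma SPUr p-values).
#' @export
aspur_test <- function(sr_robust, gammas = gamma_set()) {
  if (!isTRUE(sr_robust$robust))
    stop("aspur_test expects a robust score_result (robust = TRUE)")
  out <- aspu_machinery(sr_robust, gammas)
  names(out$spu) <- sub("^spu", "spur", names(out$spu))
  out
}

#' Stage-wise adaptive resampling schedule
#'
#' Genome-scan schedule for resampling p-values: start at `b_start`
#' resamples and, while the estimated p-value is below `threshold / B`
#' (too few null exceedances for a stable estimate), multiply `B` by
#' `factor` and re-estimate, capping at `b_max`.  Defaults follow the
#' 1000 -> x10 -> 1e6 schedule with the 50/B rule.
#'
#' @param test_closure function of one argument `B` returning a p-value
#'   estimated with `B` resamples.
#' @param b_start,factor,b_max schedule parameters.
#' @param threshold escalation rule numerator (escalate while
#'   `p < threshold / B`).
#' @return list with `p` and `b_used`.
#' @export
stagewise_pvalue <- function(test_closure, b_start = 1000, factor = 10,
                             b_max = 1e6, threshold = 50) {
  stopifnot(b_start >= 1, factor > 1, b_max >= b_start)
  B <- b_start
  repeat {
    p <- test_closure(B)
    if (p >= threshold / B || B >= b_max) return(list(p = p, b_used = B))
    B <- min(B * factor, b_max)
  }
}
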