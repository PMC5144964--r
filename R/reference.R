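#' Burden (T1) test p-value
#'
#' The burden statistic is the plain sum `T = sum_j U_j`, equivalent to
#' SPU(1); its p-value uses the shared-resample two-sided rule and is
#' identical to `spu_test(sr, 1)`.
#'
#' @param sr a Gaussian [resample_null_scores()] result.
#' @return p-value.
#' @export
burden_test <- function(sr) {
  resampling_pvalue(sum(sr$u_obs), rowSums(sr$u_null))
}

#' Tail probability of a positive-definite quadratic form
#'
#' `P(sum_i lambda_i chi2_1 > q)` for nonnegative weights `lambda`.
#' `method = "liu"` (default) is the modified Liu et al. moment-matching
#' approximation to a noncentral chi-square; `method = "imhof"` inverts
#' the characteristic function numerically and serves as the
#' high-accuracy cross-check.
#'
#' @param q observed statistic.
#' @param lambda nonnegative mixture weights.
#' @param method `"liu"` or `"imhof"`.
#' @return upper-tail probability.
#' @export
pvalue_quadform <- function(q, lambda, method = c("liu", "imhof")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) return(1)
  if (method == "liu") liu_pvalue(q, lambda) else imhof_pvalue(q, lambda)
}

# modified Liu et al. (2009) moment matching, as used by SKAT
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  muX <- l + d; sigmaX <- sqrt(2) * a
  tstar <- (q - muQ) / sigmaQ
  pchisq(tstar * sigmaX + muX, df = l, ncp = d, lower.tail = FALSE)
}

# Imhof (1961) numerical inversion of the characteristic function.
# The integrand oscillates with envelope 1 / (u * prod(1 + l^2 u^2)^(1/4)),
# so it is truncated where the envelope drops below 1e-11.
imhof_pvalue <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  envelope <- function(u) 1 / (u * prod(1 + lambda^2 * u^2)^0.25)
  upper <- 1
  while (envelope(upper) > 1e-11 && upper < 1e12) upper <- upper * 2
  val <- integrate(integrand, 0, upper, rel.tol = 1e-8,
                   subdivisions = 10000L, stop.on.error = FALSE)$value
  min(max(0.5 + val / pi, 1e-14), 1)
}

#' Asymptotic linear-kernel SKAT p-value
#'
#' Variance-component score test with statistic `Q = sum_j w_j U_j^2`
#' (equal weights by default, making `Q` the SPU(2) statistic), referred
#' to its asymptotic null `sum_i lambda_i chi2_1` where the `lambda_i`
#' are the eigenvalues of `W^{1/2} V W^{1/2}`.  By default `V` is the
#' model-based covariance `sigma_gauss^2 * X' P X` (P the null-model
#' projection), as in standard SKAT; `variance = "sandwich"` substitutes
#' the empirical estimate [vhat()].  The asymptotic approximation is
#' exactly what fails under heavy-tailed or contaminated traits, which
#' is the behaviour this comparator exists to exhibit.
#'
#' @inheritParams score_vector
#' @param weights optional per-variant nonnegative weights (diagonal of
#'   W); see [beta_maf_weights()].
#' @param method tail-probability algorithm, see [pvalue_quadform()].
#' @param variance `"model"` (default) or `"sandwich"`.
#' @return p-value.
#' @export
skat_linear_pvalue <- function(nm, x, weights = NULL,
                               method = c("liu", "imhof"),
                               variance = c("model", "sandwich")) {
  method <- match.arg(method)
  variance <- match.arg(variance)
  k <- ncol(x$geno)
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(weights < 0))
    stop("weights must be k nonnegative values")
  u <- score_vector(nm, x)
  qstat <- sum(weights * u^2)
  if (variance == "model") {
    xp <- x$geno - nm$qthin %*% crossprod(nm$qthin, x$geno)
    v <- nm$sigma_gauss^2 * crossprod(xp)
  } else {
    v <- vhat(nm, x)
  }
  sw <- sqrt(weights)
  m <- v * outer(sw, sw)
  lambda <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 0 & lambda > -1e-10 * max(abs(lambda), 1)] <- 0
  lambda <- pmax(lambda, 0)
  if (all(lambda < .Machine$double.eps * max(1, qstat))) {
    warning("all eigenvalues ~ 0; returning p = 1")
    return(1)
  }
  pvalue_quadform(qstat, lambda, method)
}

#' Beta-density MAF weights
#'
#' The SKAT weighting convention: the diagonal of W is the squared
#' Beta(a, b) density evaluated at each variant's MAF.  The default
#' Beta(1, 25) strongly upweights the rarest variants; `a = b = 1`
#' recovers equal weights.  Provided as an optional hook; the package's
#' headline tests are unweighted.
#'
#' @param mafs minor-allele frequencies in (0, 0.5].
#' @param a,b Beta shape parameters.
#' @return per-variant weights.
#' @export
beta_maf_weights <- function(mafs, a = 1, b = 25) {
  mafs <- as.numeric(mafs)
  if (any(mafs <= 0)) stop("maf = 0: filter monomorphic variants first")
  if (any(mafs > 0.5)) stop("mafs must be minor-allele frequencies (<= 0.5)")
  dbeta(mafs, a, b)^2
}

#' Genomic-control lambda and QQ coordinates
#'
#' Converts p-values to 1-df chi-square quantiles and divides their
#' median by the null median 0.4549; lambda near 1 indicates calibrated
#' tests, lambda > 1 genome-wide inflation.  Also returns the
#' `-log10` expected-vs-observed QQ coordinates.
#'
#' @param pvalues vector of at least 10 p-values in (0, 1].
#' @return list of class `gc_lambda`: `lambda` and `qq` (data frame with
#'   columns `expected`, `observed`, both on the -log10 scale).
#' @export
genomic_control_lambda <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) < 10L) stop("need at least 10 p-values")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1] (resampling p-values never reach 0)")
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  lam <- median(chi) / qchisq(0.5, df = 1)
  m <- length(p)
  qq <- data.frame(expected = -log10(seq_len(m) / (m + 1)),
                   observed = -log10(sort(p)))
  structure(list(lambda = lam, qq = qq), class = "gc_lambda")
}

#' @export
print.gc_lambda <- function(x, ...) {
  cat(sprintf("genomic control lambda = %.3f (%d p-values)\n",
              x$lambda, nrow(x$qq)))
  invisible(x)
}
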