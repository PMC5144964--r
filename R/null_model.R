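#' Fit the null model of a quantitative trait on covariates
#'
#' Least-squares fit of `y` on an intercept plus optional covariates
#' `z`; under the no-association null this supplies the fitted means and
#' residuals that every score-based test in the package is built from.
#' Both the Gaussian residual scale and the robust MAD-based scale are
#' stored, together with the thin Q factor of the design used to project
#' resampled traits back onto the residual space.
#'
#' @param y numeric trait vector.
#' @param z optional n x q covariate matrix (no intercept column).
#' @return An object of class `rv_null_model` with elements `fitted`,
#'   `residuals`, `coefficients`, `sigma_gauss` (residual SD),
#'   `sigma_mad` (MAD/0.6745 of the residuals), `q` (number of
#'   covariates), `n`, and `qthin`.
#' @examples
#' nm <- fit_null(c(1, 2, 3))
#' nm$fitted     # 2 2 2
#' nm$residuals  # -1 0 1
#' @export
fit_null <- function(y, z = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("trait contains non-finite values")
  if (!is.null(z)) {
    z <- as.matrix(z)
    storage.mode(z) <- "double"
    if (nrow(z) != n) stop("covariate rows must match trait length")
    if (ncol(z) == 0L) z <- NULL
  }
  design <- cbind(`(Intercept)` = rep(1, n), z)
  p <- ncol(design)
  if (n <= p) stop("need n > q + 1 subjects to fit the null model")
  qrd <- qr(design)
  if (qrd$rank < p) stop("rank-deficient design (collinear covariates)")
  coef <- qr.coef(qrd, y)
  fitted <- as.numeric(design %*% coef)
  res <- y - fitted
  structure(
    list(fitted = fitted, residuals = res, coefficients = coef,
         sigma_gauss = sqrt(sum(res^2) / (n - p)),
         sigma_mad = mad_sigma(res),
         q = p - 1L, n = n, qthin = qr.Q(qrd)),
    class = "rv_null_model")
}

#' @export
print.rv_null_model <- function(x, ...) {
  cat(sprintf(
    "null model: n = %d, q = %d covariate(s), sigma_gauss = %.4g, sigma_mad = %.4g\n",
    x$n, x$q, x$sigma_gauss, x$sigma_mad))
  invisible(x)
}

#' Robust MAD scale estimate
#'
#' Median absolute deviation about the median divided by 0.6745, the
#' constant that makes it a consistent estimate of sigma for Gaussian
#' data.  A zero result (at least half the values identical) is returned
#' as-is but flagged with attribute `degenerate = TRUE`; robust scoring
#' refuses to divide by it and instructs the caller to fall back.
#'
#' @param values numeric vector, length >= 2.
#' @return non-negative scalar, attribute `degenerate` when zero.
#' @examples
#' mad_sigma(1:5)  # 1 / 0.6745
#' @export
mad_sigma <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  s <- median(abs(values - median(values))) / 0.6745
  if (s == 0) attr(s, "degenerate") <- TRUE
  s
}

#' Gaussian score vector
#'
#' `U_j = sum_i r_i X_ij` with `r` the null-model residuals (which
#' reduce to `Y_i - Ybar` without covariates).  This is the score of the
#' Gaussian likelihood at the null and the common building block of the
#' burden, SKAT and SPU statistics; no scaling by sigma is applied.
#'
#' @param nm an [fit_null()] object.
#' @param x a [variant_set] with `nm$n` rows.
#' @return numeric vector of length `k`.
#' @export
score_vector <- function(nm, x) {
  if (nrow(x$geno) != nm$n) stop("genotype rows must match the null model")
  as.numeric(crossprod(x$geno, nm$residuals))
}

#' Empirical covariance of the score vector
#'
#' The sandwich estimate `Vhat = sum_i r_i^2 (X_i - Xbar)(X_i - Xbar)'`,
#' symmetric and positive semidefinite up to roundoff.
#'
#' @inheritParams score_vector
#' @return k x k matrix.
#' @export
vhat <- function(nm, x) {
  if (nrow(x$geno) != nm$n) stop("genotype rows must match the null model")
  xc <- sweep(x$geno, 2, colMeans(x$geno))
  v <- crossprod(xc, xc * nm$residuals^2)
  (v + t(v)) / 2
}

huber_psi <- function(u, c) pmin(pmax(u, -c), c)

#' Huber robust score vector
#'
#' `U_H = sum_i psi_c(r_i / sigma) X_i.` where `psi_c(u) = u` for
#' `|u| <= c` and `c * sign(u)` otherwise: each subject's contribution
#' is bounded in norm by `c * ||X_i.||`, which removes the undue
#' influence of outlying trait values on the score.  The default
#' `c = 1.345` retains 95% asymptotic efficiency under Gaussian errors;
#' the scale is the null model's MAD estimate unless overridden.
#'
#' @inheritParams score_vector
#' @param c Huber truncation constant.
#' @param sigma robust scale; defaults to `nm$sigma_mad`.
#' @return numeric vector of length `k`.
#' @export
huber_score <- function(nm, x, c = 1.345, sigma = NULL) {
  if (nrow(x$geno) != nm$n) stop("genotype rows must match the null model")
  if (is.null(sigma)) sigma <- nm$sigma_mad
  if (!is.numeric(sigma) || sigma <= 0)
    stop("degenerate MAD scale (sigma = 0); fall back to the Gaussian score ",
         "or supply sigma explicitly")
  as.numeric(crossprod(x$geno, huber_psi(nm$residuals / sigma, c)))
}

#' Resample null score vectors
#'
#' Generates `B` null trait vectors `Y^(b)` from the fitted null model
#' and computes the (Gaussian or Huber) score vector of each with the
#' null-model fitted means held fixed, i.e. from `Y^(b) - mu_hat`.
#' Holding the fit fixed makes residual permutation an exact permutation
#' test of the per-subject scores (for both the linear and the Huber
#' score).  In robust mode the MAD scale is recomputed per resample
#' (set `recompute_mad = FALSE` to freeze it at the observed value);
#' under residual permutation the two coincide, since the residual
#' multiset is permutation invariant.
#'
#' Modes: `permute_residuals` (default) shuffles the null residuals and
#' adds them to the fitted means; `permute_y` permutes the raw trait and
#' is valid only without covariates; `parametric_bootstrap` draws iid
#' `N(0, sigma_gauss^2)` errors.
#'
#' @inheritParams score_vector
#' @param B number of resamples.
#' @param mode resampling scheme (see Details).
#' @param robust use the Huber score instead of the Gaussian score.
#' @param seed optional integer seed for reproducibility.
#' @param huber_c Huber truncation constant (robust mode).
#' @param recompute_mad recompute the MAD scale on each resample.
#' @param .rnull precomputed null residual matrix (internal; lets the
#'   Gaussian and robust scores share one resample draw).
#' @return An object of class `score_result`: `u_obs` (length k),
#'   `u_null` (B x k), `b_used`, `robust`, `mode`, `seed`.
#' @export
resample_null_scores <- function(nm, x, B,
                                 mode = c("permute_residuals", "permute_y",
                                          "parametric_bootstrap"),
                                 robust = FALSE, seed = NULL,
                                 huber_c = 1.345, recompute_mad = TRUE,
                                 .rnull = NULL) {
  mode <- match.arg(mode)
  stopifnot(B >= 1)
  if (nrow(x$geno) != nm$n) stop("genotype rows must match the null model")
  if (mode == "permute_y" && nm$q > 0)
    stop("permute_y is valid only without covariates; use permute_residuals ",
         "or parametric_bootstrap")
  n <- nm$n
  if (is.null(.rnull)) {
    if (!is.null(seed)) set.seed(seed)
    rnull <- null_residual_matrix(nm, B, mode)
  } else {
    rnull <- .rnull
    stopifnot(nrow(rnull) == n, ncol(rnull) == B)
  }
  if (!robust) {
    u_null <- crossprod(rnull, x$geno)
    u_obs <- score_vector(nm, x)
  } else {
    if (recompute_mad) {
      sig <- col_mad_sigma(rnull)
      if (any(sig <= 0))
        stop("degenerate MAD scale in a resample; robust scoring needs a ",
             "continuous trait")
    } else {
      if (nm$sigma_mad <= 0) stop("degenerate MAD scale (sigma = 0)")
      sig <- rep(nm$sigma_mad, B)
    }
    psi <- huber_psi_cols(rnull, sig, huber_c)
    u_null <- crossprod(psi, x$geno)
    u_obs <- huber_score(nm, x, c = huber_c)
  }
  structure(list(u_obs = u_obs, u_null = u_null, b_used = B,
                 robust = robust, mode = mode, seed = seed,
                 huber_c = if (robust) huber_c else NA_real_),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("score_result: k = %d, B = %d resamples (%s, %s score)\n",
              length(x$u_obs), x$b_used, x$mode,
              if (x$robust) "Huber" else "Gaussian"))
  invisible(x)
}

# per-column MAD/0.6745 (Rcpp-backed medians; hot path of robust resampling)
col_mad_sigma <- function(m) {
  med <- col_medians(m)
  dev <- abs(m - rep(med, each = nrow(m)))
  col_medians(dev) / 0.6745
}

# B resampled null-trait residual vectors Y^(b) - mu_hat as an n x B
# matrix.  The null statistic is computed with the null-model fitted
# means held fixed (no per-resample refit), so permuting residuals
# yields an exact permutation test of the per-subject scores --
# essential for the nonlinear Huber score, whose calibration degrades
# under a refit.  permute_y (q = 0 only) subtracts the grand mean and
# reduces to the same draw as permute_residuals.
null_residual_matrix <- function(nm, B, mode) {
  if (mode == "parametric_bootstrap")
    matrix(rnorm(nm$n * B, 0, nm$sigma_gauss), nm$n, B)
  else perm_columns(nm$residuals, B)
}
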