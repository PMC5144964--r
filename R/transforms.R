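#' Natural-log transform of a trait
#'
#' Elementwise natural logarithm, the standard variance-stabilizing
#' transform for right-skewed positive traits such as triglycerides.
#' Non-positive values are an error: no silent offset is added.
#'
#' @param y numeric trait vector, all values > 0.
#' @return transformed vector with attribute `transform = "ln"`.
#' @export
transform_ln <- function(y) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("trait contains non-finite values")
  if (any(y <= 0)) stop("transform_ln requires strictly positive values")
  structure(log(y), transform = "ln")
}

#' Rank-based inverse-normal transform
#'
#' Maps the trait through its ranks to standard-normal quantiles:
#' `y_i -> qnorm((r_i - c0) / (n - 2*c0 + 1))` with average ranks for
#' ties and the Blom offset `c0 = 3/8` by default.  The result depends
#' only on the ordering of `y`, so it is invariant to any strictly
#' increasing transform of the input.
#'
#' @param y numeric trait vector, length >= 2, not all values equal.
#' @param offset rank offset `c0` (3/8 = Blom; 1/3 = Tukey; 1/2 =
#'   Hazen/van der Waerden variants).
#' @return transformed vector with attribute `transform = "inv_normal"`.
#' @export
transform_inverse_normal <- function(y, offset = 3/8) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations")
  if (any(!is.finite(y))) stop("trait contains non-finite values")
  if (diff(range(y)) == 0)
    stop("all trait values identical; ranks carry no information")
  r <- rank(y, ties.method = "average")
  structure(qnorm((r - offset) / (n - 2 * offset + 1)),
            transform = "inv_normal")
}

#' Winsorize a trait at the alpha1 quantile band
#'
#' Values below the empirical `alpha1` quantile are pulled up to that
#' quantile and values above the `1 - alpha1` quantile pulled down to it;
#' the length is unchanged.  Quantiles use the linear-interpolation
#' convention (`quantile(..., type = 7)`).  By default Winsorizing acts
#' on the raw trait values, ignoring covariates — the usual ad hoc
#' practice; set `residual_based = TRUE` (with `z`) to Winsorize the
#' covariate-adjusted residuals instead and add the fitted means back.
#'
#' @param y numeric trait vector.
#' @param alpha1 tail fraction, in (0, 0.5).
#' @param z optional covariate matrix used only when `residual_based`.
#' @param residual_based Winsorize null-model residuals rather than `y`.
#' @return Winsorized vector with attribute `transform = "winsorized"`.
#' @export
winsorize <- function(y, alpha1, z = NULL, residual_based = FALSE) {
  stopifnot(alpha1 > 0, alpha1 < 0.5)
  y <- as.numeric(y)
  if (residual_based) {
    nm <- fit_null(y, z)
    r <- winsorize(nm$residuals, alpha1)
    return(structure(nm$fitted + as.numeric(r), transform = "winsorized"))
  }
  qs <- quantile(y, c(alpha1, 1 - alpha1), type = 7, names = FALSE)
  structure(pmin(pmax(y, qs[1]), qs[2]), transform = "winsorized")
}

#' Trim subjects with extreme trait values
#'
#' Subjects whose trait lies outside the empirical
#' `[alpha1, 1 - alpha1]` quantile band (same type-7 convention as
#' [winsorize()]) are removed jointly from the trait, the genotype set,
#' and the covariates, keeping all objects row-aligned.
#'
#' @param y numeric trait vector.
#' @param x a [variant_set] with matching rows.
#' @param z optional covariate matrix.
#' @param alpha1 tail fraction, in (0, 0.5).
#' @return list with elements `y`, `x`, `z`, and `removed` (the dropped
#'   subject indices).
#' @export
trim <- function(y, x, z = NULL, alpha1 = 0.025) {
  stopifnot(alpha1 > 0, alpha1 < 0.5)
  y <- as.numeric(y)
  if (length(y) != nrow(x$geno)) stop("y and x have different subject counts")
  if (!is.null(z) && nrow(z) != length(y)) stop("z rows must match y")
  qs <- quantile(y, c(alpha1, 1 - alpha1), type = 7, names = FALSE)
  keep <- y >= qs[1] & y <= qs[2]
  if (sum(keep) < 3L) stop("fewer than 3 subjects remain after trimming")
  list(y = structure(y[keep], transform = "trimmed"),
       x = variant_set(x$geno[keep, , drop = FALSE], x$variant_ids, x$set_id),
       z = if (!is.null(z)) z[keep, , drop = FALSE],
       removed = which(!keep))
}
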