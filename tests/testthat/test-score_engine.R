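test_that("fit_null recovers means, residuals and coefficients", {
  nm <- fit_null(c(1, 2, 3))
  expect_equal(nm$fitted, rep(2, 3))
  expect_equal(nm$residuals, c(-1, 0, 1))
  expect_equal(nm$q, 0L)
  # exact covariate fit: zero residuals
  z <- matrix(1:6, 6, 1)
  nm2 <- fit_null(2 * as.numeric(z), z)
  expect_equal(nm2$residuals, rep(0, 6), tolerance = 1e-12)
  # OLS recovery at n = 400
  set.seed(21)
  zz <- matrix(rnorm(800), 400, 2)
  y <- as.numeric(zz %*% c(1, -1)) + rnorm(400)
  nm3 <- fit_null(y, zz)
  se <- sqrt(diag(solve(crossprod(cbind(1, zz)))) * nm3$sigma_gauss^2)
  expect_true(all(abs(nm3$coefficients[2:3] - c(1, -1)) < 3 * se[2:3]))
  expect_lt(abs(sum(nm3$residuals)), 1e-8)
  expect_error(fit_null(rnorm(10), matrix(1, 10, 2)), "rank")
})

test_that("score_vector matches the brute-force double loop", {
  nm <- fit_null(c(1, 2, 3))
  x1 <- variant_set(matrix(c(0, 0, 1), 3, 1))
  expect_equal(score_vector(nm, x1), 1)  # (3 - 2) * 1
  expect_equal(score_vector(nm, variant_set(matrix(c(0, 0, 0, 1, 1, 0), 3, 2))),
               c(0, -1))
  d <- random_dataset(31, covar = TRUE)
  nm2 <- fit_null(d$y, d$z)
  u <- score_vector(nm2, d$x)
  oracle <- vapply(seq_len(ncol(d$x$geno)), function(j) {
    s <- 0
    for (i in seq_along(d$y)) s <- s + nm2$residuals[i] * d$x$geno[i, j]
    s
  }, 0)
  expect_equal(u, oracle)
  expect_error(score_vector(nm2, toy_variant_set()), "match")
})

test_that("vhat is the printed sandwich formula, symmetric PSD", {
  # 3-subject toy, evaluated by hand from the formula
  nm <- fit_null(c(1, 2, 3))
  x <- variant_set(matrix(c(0, 0, 1), 3, 1))
  # residuals (-1, 0, 1), xbar = 1/3:
  # Vhat = 1*(0-1/3)^2 + 0 + 1*(1-1/3)^2 = 1/9 + 4/9
  expect_equal(vhat(nm, x)[1, 1], 5 / 9)
  # zero residuals -> zero matrix
  z <- matrix(1:6, 6, 1)
  nmz <- fit_null(2 * as.numeric(z), z)
  x6 <- variant_set(matrix(rbinom(12, 2, 0.4), 6, 2))
  expect_equal(unname(vhat(nmz, x6)), matrix(0, 2, 2), tolerance = 1e-12)
  # PSD on random instances
  for (s in 1:5) {
    d <- random_dataset(100 + s, covar = TRUE)
    v <- vhat(fit_null(d$y, d$z), d$x)
    expect_equal(v, t(v))
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(abs(ev)))
  }
})

test_that("mad_sigma follows the 0.6745 convention and is consistent", {
  expect_equal(mad_sigma(1:5), 1 / 0.6745)
  s0 <- mad_sigma(rep(3, 4))
  expect_equal(as.numeric(s0), 0)
  expect_true(isTRUE(attr(s0, "degenerate")))
  set.seed(41)
  expect_lt(abs(mad_sigma(rnorm(1e5)) - 1), 0.02)
})

test_that("huber_score truncates contributions at c and has bounded influence", {
  # single-subject contributions with sigma = 1
  mk <- function(res) {
    nm <- fit_null(res + 5)          # intercept-only: residuals = res - mean
    nm$residuals <- res              # force exact residuals for the check
    nm$sigma_mad <- 1
    nm
  }
  x <- variant_set(rbind(c(1, 0), c(0, 1), c(0, 0)))
  nm <- mk(c(0.5, 0, 0))
  expect_equal(huber_score(nm, x), c(0.5, 0))
  expect_equal(huber_score(mk(c(10, 0, 0)), x), c(1.345, 0))
  expect_equal(huber_score(mk(c(-10, 0, 0)), x), c(-1.345, 0))
  # c -> Inf limit reproduces U / sigma_mad
  d <- random_dataset(51)
  nm2 <- fit_null(d$y)
  expect_equal(huber_score(nm2, d$x, c = 1e6),
               score_vector(nm2, d$x) / nm2$sigma_mad, tolerance = 1e-10)
  # bounded influence: each subject's contribution has norm <= c||X_i.||
  # whatever the outlier magnitude, and the total score saturates as the
  # outlier grows (no divergence, unlike the Gaussian score)
  uh_at <- function(mag) { y2 <- d$y; y2[1] <- mag; huber_score(fit_null(y2), d$x) }
  for (mag in c(1e2, 1e6, 1e12)) {
    y2 <- d$y; y2[1] <- mag
    nmo <- fit_null(y2)
    contrib <- rvrobust:::huber_psi(nmo$residuals[1] / nmo$sigma_mad, 1.345) *
      d$x$geno[1, ]
    expect_lte(sqrt(sum(contrib^2)),
               1.345 * sqrt(sum(d$x$geno[1, ]^2)) + 1e-12)
  }
  expect_equal(uh_at(1e6), uh_at(1e12), tolerance = 1e-4)
  ug_at <- function(mag) { y2 <- d$y; y2[1] <- mag; score_vector(fit_null(y2), d$x) }
  expect_gt(max(abs(ug_at(1e12) - ug_at(1e6))), 1e10)  # Gaussian diverges
  expect_error(huber_score(nm2, d$x, sigma = 0), "degenerate|sigma")
})

test_that("resampling is reproducible and permutation-faithful", {
  d <- random_dataset(61, covar = TRUE)
  nm <- fit_null(d$y, d$z)
  s1 <- resample_null_scores(nm, d$x, B = 3, seed = 9)
  s2 <- resample_null_scores(nm, d$x, B = 3, seed = 9)
  expect_identical(s1$u_null, s2$u_null)
  expect_equal(dim(s1$u_null), c(3L, ncol(d$x$geno)))
  expect_true(all(is.finite(s1$u_null)))
  # permuted-residual null traits keep the residual multiset (q = 0 case)
  nm0 <- fit_null(d$y)
  set.seed(12)
  rn <- rvrobust:::null_residual_matrix(nm0, 5, "permute_residuals")
  for (b in 1:5)
    expect_equal(sort(rn[, b]), sort(nm0$residuals), tolerance = 1e-12)
  # null scores are mean-zero: B = 1e4 resamples
  s3 <- resample_null_scores(nm0, d$x, B = 1e4, seed = 10)
  se <- apply(s3$u_null, 2, sd) / sqrt(1e4)
  expect_true(all(abs(colMeans(s3$u_null)) < 3.5 * se + 1e-12))
  expect_error(resample_null_scores(nm, d$x, 5, mode = "permute_y"),
               "permute_y")
})

test_that("robust resampling recomputes MAD per resample by default", {
  d <- random_dataset(71, covar = TRUE)
  nm <- fit_null(d$y, d$z)
  # under residual permutation the residual multiset -- hence the MAD --
  # is invariant, so recomputed and frozen scales coincide exactly
  sr <- resample_null_scores(nm, d$x, B = 50, robust = TRUE, seed = 3)
  sf <- resample_null_scores(nm, d$x, B = 50, robust = TRUE, seed = 3,
                             recompute_mad = FALSE)
  expect_equal(sr$u_null, sf$u_null, tolerance = 1e-12)
  # under the parametric bootstrap each resample has its own scale
  sb <- resample_null_scores(nm, d$x, B = 50, robust = TRUE, seed = 3,
                             mode = "parametric_bootstrap")
  sbf <- resample_null_scores(nm, d$x, B = 50, robust = TRUE, seed = 3,
                              mode = "parametric_bootstrap",
                              recompute_mad = FALSE)
  expect_false(identical(sb$u_null, sbf$u_null))
  # same observed statistic either way
  expect_equal(sr$u_obs, sf$u_obs)
  # every robust null score is bounded by c * colsum of genotypes
  bound <- 1.345 * colSums(d$x$geno)
  expect_true(all(abs(sr$u_null) <= rep(bound, each = 50) + 1e-12))
})

test_that("permute_y and permute_residuals agree in distribution when q = 0", {
  # with no covariates the two schemes draw the same null scores
  d <- random_dataset(81)
  nm <- fit_null(d$y)
  a <- resample_null_scores(nm, d$x, B = 200, mode = "permute_y", seed = 5)
  b <- resample_null_scores(nm, d$x, B = 200, mode = "permute_residuals",
                            seed = 5)
  expect_equal(a$u_null, b$u_null, tolerance = 1e-12)
})
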