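test_that("gamma_set validates its contents", {
  expect_equal(as.numeric(gamma_set(c(3, 1, Inf))), c(1, 3, Inf))
  expect_error(gamma_set(c(1, 1)), "duplicate")
  expect_error(gamma_set(numeric(0)), "non-empty")
  expect_error(gamma_set(c(0.5)), "positive integers")
})

test_that("spu_statistic computes powered sums and the max norm", {
  u <- c(1, -2, 3)
  expect_equal(spu_statistic(u, 1), 2)
  expect_equal(spu_statistic(u, 2), 14)
  expect_equal(spu_statistic(u, Inf), 3)
})

test_that("resampling_pvalue counts ties toward the null", {
  expect_equal(resampling_pvalue(5, 1:10), 7 / 11)
  expect_equal(resampling_pvalue(-5, 1:10), 7 / 11)  # |.| comparison
  expect_equal(resampling_pvalue(99, 1:10), 1 / 11)  # floor 1/(B+1)
  expect_equal(resampling_pvalue(0, 1:10), 1)
})

make_sr <- function(u_obs, u_null, robust = FALSE) {
  structure(list(u_obs = u_obs, u_null = u_null, b_used = nrow(u_null),
                 robust = robust, mode = "permute_residuals", seed = NA),
            class = "score_result")
}

test_that("spu_test matches direct oracles on shared resamples", {
  d <- random_dataset(91, covar = TRUE)
  nm <- fit_null(d$y, d$z)
  sr <- resample_null_scores(nm, d$x, B = 200, seed = 17)
  p <- spu_test(sr, c(1:4, Inf))
  # SPU(1) equals the burden test on the same resamples
  expect_equal(unname(p["spu1"]), burden_test(sr))
  # SPU(2) equals a direct quadratic-statistic resampling p
  q_obs <- sum(sr$u_obs^2)
  q_null <- rowSums(sr$u_null^2)
  expect_equal(unname(p["spu2"]), (sum(q_null >= q_obs) + 1) / 201)
  # per-gamma oracle through the generic formula
  for (g in c(1, 3, Inf)) {
    t_obs <- spu_statistic(sr$u_obs, g)
    t_null <- apply(sr$u_null, 1, spu_statistic, gamma = g)
    expect_equal(unname(p[[paste0("spu", ifelse(is.finite(g), g, "inf"))]]),
                 resampling_pvalue(t_obs, t_null))
  }
})

test_that("k = 1 collapses SPU p-values by parity of gamma", {
  set.seed(14)
  sr <- make_sr(1.3, matrix(rnorm(100), 100, 1))
  p <- spu_test(sr, 1:6)
  expect_equal(unname(p[c("spu1", "spu3", "spu5")]), rep(p[["spu1"]], 3))
  expect_equal(unname(p[c("spu2", "spu4", "spu6")]), rep(p[["spu2"]], 3))
  # |.|-based two-sided comparison makes odd and even agree at k = 1 too
  expect_equal(p[["spu1"]], p[["spu2"]])
})

test_that("p-values are invariant to monotone transforms of the statistic", {
  d <- random_dataset(92)
  nm <- fit_null(d$y)
  sr <- resample_null_scores(nm, d$x, B = 150, seed = 2)
  for (g in c(2, 3)) {
    t_obs <- spu_statistic(sr$u_obs, g)
    t_null <- apply(sr$u_null, 1, spu_statistic, gamma = g)
    p_raw <- resampling_pvalue(t_obs, t_null)
    # the gamma-th root (of |T|, sign kept for odd gamma) is monotone in |T|
    root <- function(t) sign(t) * abs(t)^(1 / g)
    expect_identical(p_raw, resampling_pvalue(root(t_obs), root(t_null)))
  }
})

test_that("aspu_test reproduces the brute-force double-rank oracle", {
  # tiny hand-checkable instance: B = 5, two gammas
  u_obs <- c(2, -1)
  u_null <- rbind(c(1, 0), c(-3, 1), c(0, 2), c(2, 2), c(-1, -1))
  sr <- make_sr(u_obs, u_null)
  res <- aspu_test(sr, c(1, 2))
  # independent brute-force oracle over the 5 resamples
  gam <- c(1, 2)
  B <- 5
  t_obs <- sapply(gam, function(g) spu_statistic(u_obs, g))
  t_null <- sapply(gam, function(g) apply(u_null, 1, spu_statistic, gamma = g))
  p_obs <- sapply(seq_along(gam), function(j)
    (sum(abs(t_null[, j]) >= abs(t_obs[j])) + 1) / (B + 1))
  p_null <- matrix(NA, B, 2)
  for (b in 1:B) for (j in 1:2)
    p_null[b, j] <- (sum(abs(t_null[-b, j]) >= abs(t_null[b, j])) + 1) / B
  aspu_oracle <- (sum(apply(p_null, 1, min) <= min(p_obs)) + 1) / (B + 1)
  expect_equal(res$spu, setNames(p_obs, c("spu1", "spu2")))
  expect_equal(res$p, aspu_oracle)
})

test_that("singleton gamma set reduces aSPU to that SPU p-value", {
  d <- random_dataset(93)
  sr <- resample_null_scores(fit_null(d$y), d$x, B = 400, seed = 8)
  res <- aspu_test(sr, 2)
  expect_lt(abs(res$p - res$spu[["spu2"]]), 1.5 / 401)
})

test_that("aSPU p is bracketed by the min-p bounds", {
  set.seed(15)
  for (rep in 1:60) {
    k <- sample(1:5, 1); B <- sample(20:80, 1)
    sr <- make_sr(rnorm(k, sd = 2), matrix(rnorm(B * k), B, k))
    gam <- c(1, 2, 3, Inf)
    res <- aspu_test(sr, gam)
    minp <- min(res$spu)
    expect_gte(res$p, minp - 1e-12)
    expect_lte(res$p, length(gam) * minp + 2 / (B + 1) + 1e-12)
  }
})

test_that("aspur equals aspu in the no-outlier large-c limit (q = 0)", {
  # with q = 0 and permuted residuals the MAD is multiset-invariant, so
  # c = 1e6 rescales every statistic identically and p-values match exactly
  d <- random_dataset(94, n = 60, k = 3)
  nm <- fit_null(d$y)
  set.seed(30)
  rn <- rvrobust:::null_residual_matrix(nm, 300, "permute_residuals")
  srg <- resample_null_scores(nm, d$x, 300, .rnull = rn)
  srr <- resample_null_scores(nm, d$x, 300, robust = TRUE, huber_c = 1e6,
                              .rnull = rn)
  ag <- aspu_test(srg, c(1:4, Inf))
  ar <- aspur_test(srr, c(1:4, Inf))
  expect_equal(ar$p, ag$p)
  expect_equal(unname(ar$spu), unname(ag$spu))
  expect_error(aspur_test(srg), "robust")
  expect_error(aspu_test(srr), "Gaussian")
})

test_that("stagewise schedule follows the 50/B escalation rule", {
  # p at B = 1000 is 0.4 -> stop immediately
  calls <- 0
  res <- stagewise_pvalue(function(B) { calls <<- calls + 1; 0.4 })
  expect_equal(res, list(p = 0.4, b_used = 1000))
  expect_equal(calls, 1)
  # p = 0.01 < 50/1000 at B = 1000 escalates, then stops at B = 1e4
  res2 <- stagewise_pvalue(function(B) 0.01)
  expect_equal(res2$b_used, 1e4)
  # a tiny p keeps escalating to the cap
  res3 <- stagewise_pvalue(function(B) 1e-5)
  expect_equal(res3$b_used, 1e6)
  # rigged closure whose estimate sharpens with B
  res4 <- stagewise_pvalue(function(B) max(2e-4, 1 / B))
  expect_equal(res4$b_used, 1e6)
  expect_equal(res4$p, 2e-4)
})
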