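#' Run a battery of set-based tests on one dataset
#'
#' Fits the null model (after the requested trait transform), builds the
#' shared Gaussian and/or robust resample matrices once, and returns the
#' p-value of every requested test.  All resampling tests see the same
#' resamples, and the robust resamples reuse the Gaussian permutation
#' seed, so comparisons across tests are paired.
#'
#' Test names: `"aspu"`, `"aspur"`, `"burden"` (T1), `"skat"`
#' (asymptotic linear-kernel, equal weights), `"spu<g>"` /
#' `"spur<g>"` for individual exponents (e.g. `"spu2"`, `"spuinf"`).
#'
#' @param x a [variant_set] (monomorphic variants are dropped silently).
#' @param y trait vector.
#' @param z optional covariate matrix.
#' @param tests character vector of test names.
#' @param B resamples for the SPU-family tests.
#' @param gammas gamma set for aSPU/aSPUr.
#' @param transform `"none"`, `"inv"` or `"ln"` (see [sim_scenario()]).
#' @param mode resampling mode, see [resample_null_scores()].
#' @param huber_c Huber constant for the robust tests.
#' @param seed optional seed shared by the Gaussian and robust resamples.
#' @return named numeric vector of p-values.
#' @export
run_tests_once <- function(x, y, z = NULL, tests = c("aspu", "aspur", "skat"),
                           B = 1000, gammas = gamma_set(),
                           transform = c("none", "inv", "ln"),
                           mode = "permute_residuals", huber_c = 1.345,
                           seed = NULL) {
  transform <- match.arg(transform)
  x <- drop_monomorphic(x, quiet = TRUE)
  if (is.null(x)) stop("no polymorphic variant left in the set")
  if (transform == "inv") {
    # regress covariates out under H0, then inverse-normal the residuals
    # and test them without covariates
    y <- transform_inverse_normal(fit_null(y, z)$residuals)
    z <- NULL
  } else if (transform == "ln") {
    y <- transform_ln(y)
  }
  nm <- fit_null(y, z)
  gammas <- gamma_set(gammas)
  spu_names <- paste0("spu", ifelse(is.finite(gammas), gammas, "inf"))
  spur_names <- sub("^spu", "spur", spu_names)
  need_g <- any(tests %in% c("aspu", "burden", spu_names))
  need_r <- any(tests %in% c("aspur", spur_names))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  out <- setNames(rep(NA_real_, length(tests)), tests)
  rnull <- NULL
  if (need_g || need_r) {
    # one resample draw shared by the Gaussian and robust engines
    set.seed(seed)
    rnull <- null_residual_matrix(nm, B, mode)
  }
  if (need_g) {
    srg <- resample_null_scores(nm, x, B, mode = mode, robust = FALSE,
                                .rnull = rnull)
    ag <- aspu_machinery(srg, gammas)
    if ("aspu" %in% tests) out["aspu"] <- ag$p
    for (nmv in intersect(tests, spu_names)) out[nmv] <- ag$spu[[nmv]]
    if ("burden" %in% tests) out["burden"] <- burden_test(srg)
  }
  if (need_r) {
    srr <- resample_null_scores(nm, x, B, mode = mode, robust = TRUE,
                                huber_c = huber_c, .rnull = rnull)
    ar <- aspu_machinery(srr, gammas)
    if ("aspur" %in% tests) out["aspur"] <- ar$p
    for (nmv in intersect(tests, spur_names))
      out[nmv] <- ar$spu[[sub("^spur", "spu", nmv)]]
  }
  if ("skat" %in% tests) out["skat"] <- skat_linear_pvalue(nm, x)
  if (anyNA(out)) stop("unknown test(s): ",
                       paste(names(out)[is.na(out)], collapse = ", "))
  out
}

derive_cell_seed <- function(master_seed, cell_index) {
  as.integer((as.numeric(master_seed) * 1000003 + cell_index * 7919) %%
               2147483646) + 1L
}

run_cell <- function(scenario, tests, alpha, master_seed, cell_index,
                     keep_pvalues = FALSE) {
  set.seed(derive_cell_seed(master_seed, cell_index))
  R <- scenario$replicates
  pm <- matrix(NA_real_, R, length(tests), dimnames = list(NULL, tests))
  for (r in seq_len(R)) {
    repeat {
      ds <- tryCatch(simulate_dataset(scenario), error = function(e) {
        # contamination with no carrier: condition on a redraw
        if (grepl("carries a minor allele", conditionMessage(e))) NULL
        else stop(e)
      })
      if (is.null(ds)) next
      if (!is.null(drop_monomorphic(ds$x, quiet = TRUE))) break
    }
    pm[r, ] <- run_tests_once(ds$x, ds$y, ds$z, tests = tests,
                              B = scenario$B, transform = scenario$transform,
                              seed = sample.int(.Machine$integer.max, 1L))
  }
  rej <- colMeans(pm <= alpha)
  res <- data.frame(error_dist = scenario$error_dist,
                    param = switch(scenario$error_dist,
                                   t = scenario$df,
                                   lognormal = , contaminated = scenario$sigma_e,
                                   NA_real_),
                    k = scenario$k, transform = scenario$transform,
                    test = tests, reject = as.numeric(rej),
                    se = sqrt(rej * (1 - rej) / R),
                    replicates = R, seed = derive_cell_seed(master_seed,
                                                            cell_index),
                    row.names = NULL)
  if (keep_pvalues) attr(res, "pvalues") <- pm
  res
}

#' Empirical type-I-error grid
#'
#' For each (null) scenario, simulates `replicates` datasets and runs
#' every requested test on the same data (a paired design, so contrasts
#' between tests carry less Monte-Carlo noise), then reports the
#' fraction of p-values at or below `alpha` per cell.
#'
#' @param scenarios a [sim_scenario()] or list of them; all must have a
#'   null effect vector.
#' @param tests test names, see [run_tests_once()].
#' @param alpha nominal level.
#' @param master_seed master seed; each cell derives its own seed from
#'   it and is independently regenerable.
#' @param keep_pvalues attach the replicate-level p-value matrices as an
#'   attribute.
#' @return data frame of class `grid_result` with one row per
#'   (scenario, test): rejection fraction, Monte-Carlo SE, replicates,
#'   cell seed.
#' @export
run_type1_grid <- function(scenarios, tests = c("aspu", "aspur", "skat"),
                           alpha = 0.05, master_seed = 1,
                           keep_pvalues = FALSE) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  for (sc in scenarios)
    if (is.character(sc$beta) || any(sc$beta != 0))
      stop("run_type1_grid requires null scenarios (beta = 0)")
  run_grid(scenarios, tests, alpha, master_seed, keep_pvalues)
}

#' Empirical power grid
#'
#' Same machinery as [run_type1_grid()] for nonnull scenarios (fixed
#' `beta`, or set-ups `"I"`/`"II"` with causal variants redrawn per
#' replicate).
#'
#' @inheritParams run_type1_grid
#' @export
run_power_grid <- function(scenarios, tests = c("aspu", "aspur", "skat"),
                           alpha = 0.05, master_seed = 1,
                           keep_pvalues = FALSE) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  for (sc in scenarios)
    if (!is.character(sc$beta) && all(sc$beta == 0))
      stop("run_power_grid requires nonnull scenarios")
  run_grid(scenarios, tests, alpha, master_seed, keep_pvalues)
}

run_grid <- function(scenarios, tests, alpha, master_seed, keep_pvalues) {
  cells <- lapply(seq_along(scenarios), function(i)
    run_cell(scenarios[[i]], tests, alpha, master_seed, i, keep_pvalues))
  res <- do.call(rbind, cells)
  if (keep_pvalues)
    attr(res, "pvalues") <- lapply(cells, attr, "pvalues")
  class(res) <- c("grid_result", class(res))
  res
}

#' QQ coordinates and genomic-control lambda for a set of p-values
#'
#' @param pvalues vector of at least 10 p-values in (0, 1].
#' @return data frame with `-log10` `expected` and `observed` columns
#'   and attribute `lambda`.
#' @export
qq_table <- function(pvalues) {
  gc <- genomic_control_lambda(pvalues)
  structure(gc$qq, lambda = gc$lambda)
}
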