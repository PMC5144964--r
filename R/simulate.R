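#' Describe one simulation scenario
#'
#' Bundles every knob of a simulation cell.  Defaults are the
#' simulation-study conditions: n = 400 subjects, rare-variant MAFs
#' drawn uniformly from (0.001, 0.005), independent SNVs (`rho = 0`;
#' 0.8 gives AR-1 linkage disequilibrium), two N(0,1) covariates with
#' coefficients (1, -1), and a null effect vector.
#'
#' Error distributions: `"normal"` is N(0,1); `"lognormal"` is
#' exp(N(0, sigma_e^2)) mean-centered by subtracting exp(sigma_e^2/2)
#' (set `center_lognormal = FALSE` to skip centering); `"t"` is
#' Student t with `df` degrees of freedom (1 = Cauchy, 3 = heavy
#' tailed); `"contaminated"` is N(0,1) with one randomly chosen
#' minor-allele carrier receiving an additional independent
#' N(0, sigma_e^2) error.
#'
#' @param n,k subjects and variants.
#' @param rho AR-1 correlation of the latent haplotype Gaussian.
#' @param maf_range range of the uniform MAF draw.
#' @param error_dist one of `"normal"`, `"lognormal"`, `"t"`,
#'   `"contaminated"`.
#' @param sigma_e scale parameter of the lognormal / contamination error.
#' @param df degrees of freedom of the t error.
#' @param beta effect vector (length k), a single 0 for the null, or one
#'   of `"I"`/`"II"` to draw 8 causal variants per dataset with the
#'   mixed-sign set-up I coefficients `(-1.2,-1.2,-0.8,-0.8,0.8,1,1,1)`
#'   or the same-sign set-up II coefficients `(0.7,0.7,0.7,1,1,1,1.2,1.2)`.
#' @param covar_gamma covariate coefficients (`NULL` or `numeric(0)` for
#'   no covariates).
#' @param transform trait handling before testing: `"none"`, `"inv"`
#'   (rank inverse-normal of covariate-adjusted residuals), `"ln"`
#'   (natural log of the raw trait; requires positivity).
#' @param replicates,B Monte-Carlo replicates and resamples per test.
#' @param alpha nominal test level.
#' @param fixed_mafs optional vector of k MAFs to reuse across
#'   replicates instead of redrawing.
#' @param center_lognormal mean-center the lognormal error.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n = 400, k = 8, rho = 0,
                         maf_range = c(0.001, 0.005),
                         error_dist = c("normal", "lognormal", "t",
                                        "contaminated"),
                         sigma_e = 1, df = 3, beta = 0,
                         covar_gamma = c(1, -1),
                         transform = c("none", "inv", "ln"),
                         replicates = 1000, B = 1000, alpha = 0.05,
                         fixed_mafs = NULL, center_lognormal = TRUE) {
  error_dist <- match.arg(error_dist)
  transform <- match.arg(transform)
  stopifnot(n >= 2, k >= 1, rho >= 0, rho < 1,
            maf_range[1] > 0, maf_range[2] < 0.5,
            maf_range[1] <= maf_range[2])
  if (is.character(beta)) {
    beta <- match.arg(beta, c("I", "II"))
  } else {
    beta <- as.numeric(beta)
    if (length(beta) == 1L && beta == 0) beta <- rep(0, k)
    if (length(beta) != k) stop("beta must have length k (or be 0, 'I', 'II')")
  }
  if (length(covar_gamma) == 0L) covar_gamma <- NULL
  structure(list(n = n, k = k, rho = rho, maf_range = maf_range,
                 error_dist = error_dist, sigma_e = sigma_e, df = df,
                 beta = beta, covar_gamma = covar_gamma,
                 transform = transform, replicates = replicates, B = B,
                 alpha = alpha, fixed_mafs = fixed_mafs,
                 center_lognormal = center_lognormal),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  bd <- if (is.character(x$beta)) paste0("set-up ", x$beta)
        else if (all(x$beta == 0)) "null" else "custom beta"
  cat(sprintf(
    "sim_scenario: n=%d k=%d rho=%.2f %s(%s) %s, transform=%s, %d reps, B=%d\n",
    x$n, x$k, x$rho, x$error_dist,
    switch(x$error_dist, t = paste0("df=", x$df),
           lognormal = , contaminated = paste0("sigma_e=", x$sigma_e),
           ""), bd, x$transform, x$replicates, x$B))
  invisible(x)
}

#' Simulate rare-variant genotypes from a latent Gaussian haplotype model
#'
#' For each haplotype, a k-dimensional latent vector is drawn from
#' N(0, V) with AR-1(`rho`) correlation `V[j, l] = rho^|j - l|` and
#' dichotomized at the per-variant threshold `qnorm(1 - MAF_j)`: latent
#' values above the threshold carry the minor allele.  Two independent
#' haplotypes are summed to an unphased genotype in {0, 1, 2}.  MAFs are
#' drawn once per dataset from `U(maf_range)` unless supplied.
#' Monomorphic columns are kept (they are common at these MAFs with
#' n = 400); the test layer drops them.
#'
#' @inheritParams sim_scenario
#' @param mafs optional fixed MAF vector of length k.
#' @param seed optional seed.
#' @return a [variant_set] with attribute `design_mafs`.
#' @export
simulate_genotypes <- function(n = 400, k = 8, rho = 0,
                               maf_range = c(0.001, 0.005), mafs = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mafs)) mafs <- runif(k, maf_range[1], maf_range[2])
  stopifnot(length(mafs) == k, all(mafs > 0), all(mafs < 0.5))
  thr <- qnorm(1 - mafs)
  draw_latent <- function() {
    l <- matrix(rnorm(n * k), n, k)
    if (rho > 0) {
      rchol <- chol(rho^abs(outer(seq_len(k), seq_len(k), "-")))
      l <- l %*% rchol
    }
    l
  }
  hap1 <- sweep(draw_latent(), 2, thr, ">")
  hap2 <- sweep(draw_latent(), 2, thr, ">")
  vs <- variant_set(hap1 + hap2, set_id = "sim")
  attr(vs, "design_mafs") <- mafs
  vs
}

#' Simulate a quantitative trait for a genotype set
#'
#' `Y_i = X_i beta + Z_i gamma + eps_i` with the scenario's error
#' distribution (see [sim_scenario()]).  In the contaminated scenario
#' one subject carrying at least one minor allele is chosen uniformly at
#' random and receives an extra independent N(0, sigma_e^2) error; it is
#' an error if no carrier exists.  The base trait draw is made before
#' any contamination draw, so under a shared seed the contaminated and
#' uncontaminated traits differ in exactly that one subject.
#'
#' @param x a [variant_set].
#' @param scenario a [sim_scenario()].
#' @param seed optional seed.
#' @return list with `y` (trait vector), `z` (covariate matrix or
#'   `NULL`), `beta` (effect vector used), and `contaminated_subject`
#'   (index or `NA`).
#' @export
simulate_trait <- function(x, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x$geno); k <- ncol(x$geno)
  beta <- scenario$beta
  if (is.character(beta)) beta <- choose_causal(beta, k)
  z <- NULL
  mu <- as.numeric(x$geno %*% beta)
  if (!is.null(scenario$covar_gamma)) {
    q <- length(scenario$covar_gamma)
    z <- matrix(rnorm(n * q), n, q,
                dimnames = list(NULL, paste0("z", seq_len(q))))
    mu <- mu + as.numeric(z %*% scenario$covar_gamma)
  }
  eps <- switch(scenario$error_dist,
    normal = rnorm(n),
    lognormal = {
      e <- exp(rnorm(n, 0, scenario$sigma_e))
      if (scenario$center_lognormal) e - exp(scenario$sigma_e^2 / 2) else e
    },
    t = rt(n, df = scenario$df),
    contaminated = rnorm(n))
  y <- mu + eps
  i0 <- NA_integer_
  if (scenario$error_dist == "contaminated") {
    carriers <- which(rowSums(x$geno) > 0)
    if (!length(carriers))
      stop("contaminated scenario: no subject carries a minor allele")
    i0 <- if (length(carriers) == 1L) carriers
          else carriers[sample.int(length(carriers), 1L)]
    y[i0] <- y[i0] + rnorm(1, 0, scenario$sigma_e)
  }
  list(y = y, z = z, beta = beta, contaminated_subject = i0)
}

#' Draw the causal-effect vector for a power scenario
#'
#' Samples 8 causal positions without replacement among the k variants
#' and assigns, in order, the mixed-sign set-up I coefficients
#' `(-1.2, -1.2, -0.8, -0.8, 0.8, 1, 1, 1)` (favouring direction-blind
#' quadratic tests) or the same-sign set-up II coefficients
#' `(0.7, 0.7, 0.7, 1, 1, 1, 1.2, 1.2)` (favouring the burden test);
#' all other entries are 0.
#'
#' @param beta_setup `"I"` or `"II"`.
#' @param k number of variants (>= 8).
#' @param seed optional seed.
#' @return numeric effect vector of length k.
#' @export
choose_causal <- function(beta_setup = c("I", "II"), k, seed = NULL) {
  beta_setup <- match.arg(beta_setup)
  if (k < 8L) stop("power set-ups need k >= 8 variants")
  if (!is.null(seed)) set.seed(seed)
  coefs <- if (beta_setup == "I") c(-1.2, -1.2, -0.8, -0.8, 0.8, 1, 1, 1)
           else c(0.7, 0.7, 0.7, 1, 1, 1, 1.2, 1.2)
  beta <- rep(0, k)
  beta[sample.int(k, 8L)] <- coefs
  beta
}

#' Simulate one complete dataset for a scenario
#'
#' Convenience wrapper drawing genotypes then trait/covariates from one
#' RNG stream; with a seed the whole dataset regenerates bit-identically.
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional seed.
#' @return list with `x`, `y`, `z`, `beta`, `contaminated_subject`.
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- simulate_genotypes(scenario$n, scenario$k, scenario$rho,
                          scenario$maf_range, mafs = scenario$fixed_mafs)
  tr <- simulate_trait(x, scenario)
  c(list(x = x), tr)
}
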