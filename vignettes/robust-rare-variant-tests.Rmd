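---
title: "Robust score-based rare-variant association tests: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust score-based rare-variant association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvrobust)
```

## The model and its assumptions

For a quantitative trait $Y_i$, minor-allele counts $X_{ij} \in \{0,1,2\}$
of $k$ rare variants in one gene, and covariates $Z_i$, the working model is

$$Y_i = \beta_0 + \sum_j X_{ij}\beta_j + Z_i'\gamma + \epsilon_i,$$

and the null hypothesis is $\beta = 0$.  The score vector of the Gaussian
likelihood at the null is $U = \sum_i r_i X_{i\cdot}$ with $r_i$ the
residuals of the least-squares null fit of $Y$ on $(1, Z)$.  Everything in
this package is a functional of $U$ (or of its robust counterpart):

* $T_{SPU(\gamma)} = \sum_j U_j^\gamma$, with $\gamma = \infty$ meaning
  $\max_j |U_j|$.  $\gamma = 1$ is the burden test; $\gamma = 2$ is the
  equal-weight linear-kernel SKAT statistic.
* aSPU takes $\min_\gamma P_{SPU(\gamma)}$ over a candidate set $\Gamma$
  and calibrates that minimum against the shared resamples.
* The robust variants replace $U$ by the Huber score
  $U_H = \sum_i \psi_c(r_i/\hat\sigma)X_{i\cdot}$, where
  $\psi_c(u) = \max(-c, \min(c, u))$ and
  $\hat\sigma = \mathrm{MAD}(r)/0.6745$.

The only distributional assumption the resampling tests need is
exchangeability of the errors under the null; the Gaussian assumption
matters only for the *asymptotic* SKAT comparator, and its failure under
heavy-tailed, skewed, or contaminated traits is the phenomenon the package
exists to quantify.

Why robustness matters specifically for rare variants: a singleton variant
$j$ carried by subject 1 has $U_j = r_1$, so a single aberrant trait value
is transmitted undamped into the test statistic.  Clipping at
$c\,\hat\sigma$ bounds every subject's influence on $U_H$ by
$c\,\lVert X_{i\cdot}\rVert$.

## Resampling and p-values

Null traits are generated as $Y^{(b)} = \hat\mu + \pi_b(r)$ (residual
permutation, the default) or $\hat\mu + \epsilon_b$ with
$\epsilon_b \sim N(0, \hat\sigma_g^2)$ (parametric bootstrap).  The null
statistic is computed from $Y^{(b)} - \hat\mu$ with the null fit held
fixed — the null model is *not* refit per resample.  This is a deliberate
and load-bearing choice: with the fit held fixed, residual permutation is
an exact permutation test of the per-subject scores for *any* score
function, linear or clipped.  We originally implemented the
Freedman–Lane-style variant (re-project the permuted residuals onto the
residual space of the design); for the linear score the two are provably
the same test, but for the nonlinear Huber score the refit destroys
exactness and we measured aSPUr type-I error of ~0.18 under Cauchy errors
with covariates at $k = 64$, against ~0.05 for the fixed-fit scheme.

P-values use the two-sided rule
$p = [\sum_b I(|T^{(b)}| \ge |T|) + 1]/(B+1)$; ties count toward the null,
so $p \ge 1/(B+1)$ always.  The aSPU combination computes leave-one-out
null p-values $p_\gamma^{(b)} = [\#\{b_1 \ne b: T^{(b_1)} \ge T^{(b)}\} + 1]/B$
on the same resample matrix (denominator $B$, matching the printed
formula), takes $T^{(b)}_{aSPU} = \min_\gamma p_\gamma^{(b)}$, and reports
$[\sum_b I(T^{(b)}_{aSPU} \le T_{aSPU}) + 1]/(B+1)$.  Because only ranks
matter, every SPU p-value is invariant to monotone transforms of its
statistic (e.g. the $1/\gamma$-th root), which is what makes
$\gamma = \infty$ well defined.

In robust mode the MAD scale is recomputed on each resampled trait so the
null statistic is computed exactly as the observed one.  Under residual
permutation this is a no-op (the residual multiset is invariant), which is
itself a useful invariant; under the parametric bootstrap it matters.
`recompute_mad = FALSE` freezes the observed scale instead.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `huber_c` | 1.345 | clip point in MAD units; 95% efficiency under Gaussian errors. Larger = closer to the Gaussian score; `c = 1e6` reproduces `U`/σ̂ exactly. |
| `gammas` | 1–8, ∞ | simulation-study power set. For scan data dominated by singletons, 1–6 without ∞ is the numerically stable choice. |
| `B` | 1000 | resamples; p-value floor 1/(B+1). The stage-wise schedule (×10 while p < 50/B, cap 10⁶) keeps scans cheap. |
| `alpha1` (winsorize/trim) | — | tail fraction; quantiles are type-7 (linear interpolation). The convention is documented because the band edges move under other types. |
| INV offset | 3/8 | Blom rank offset $\Phi^{-1}((r_i - 3/8)/(n + 1/4))$, average ranks for ties. |
| `variant_maf_max`, `set_mac_min` | 0.01, 5 | "rare" ceiling per variant and minimum cumulative minor-allele count per testable gene. |
| SKAT tail method | Liu | moment matching: exact at $k = 1$, ~1e-2 absolute error mid-distribution, tail-accurate. `method = "imhof"` integrates the characteristic function numerically (truncated where the envelope < 1e-11) and agrees with a 10⁶-draw Monte-Carlo mixture to MC noise. |
| SKAT variance | model | $\hat\sigma_g^2 X'PX$ as in standard SKAT; `"sandwich"` substitutes $\hat V = \sum_i r_i^2(X_i-\bar X)(X_i-\bar X)'$. The model-based choice is what exhibits the published inflation. |

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws, per haplotype, a latent
$N(0, V)$ vector with AR-1($\rho$) correlation and dichotomizes at
$\Phi^{-1}(1-\mathrm{MAF}_j)$ (latent above the threshold carries the
minor allele); two independent haplotypes sum to an unphased genotype.
MAFs are drawn once per dataset from $U(0.001, 0.005)$ and redrawn across
replicates (each replicate is an independent dataset); a `fixed_mafs`
mode exists for variance-reduction experiments.  Defaults are the stated
study conditions: $n = 400$, $\rho \in \{0, 0.8\}$, two $N(0,1)$
covariates with $\gamma = (1,-1)$, error distributions $N(0,1)$,
centered log-normal, $t_1$/$t_3$, and contaminated normal.

Decisions where the description was open:

* **Log-normal centering.** "LN(0, σₑ) with mean 0" is self-contradictory
  (a log-normal is positive).  We draw $\exp(N(0, \sigma_e^2))$ and
  subtract $\exp(\sigma_e^2/2)$ so the error has mean ~0 as the linear
  model requires; skewness and tail mass — what drives the results — are
  unaffected by the shift.  `center_lognormal = FALSE` gives the raw draw.
* **Contamination.** One subject carrying at least one minor allele,
  chosen uniformly among carriers, receives an extra independent
  $N(0, \sigma_e^2)$ error.  Tying the outlier to a carrier is what makes
  the errors non-exchangeable with respect to the genotypes — and hence
  is the one null scenario where even the exact permutation tests
  (burden, SPU, aSPU) inflate, while the clipped aSPUr does not.  A
  dataset with no carrier at all (probability ~e⁻⁶ per dataset at
  $k = 8$) raises an error; the experiment grid redraws the dataset,
  i.e. conditions on a carrier existing.
* **Monomorphic columns.** At these MAFs with $n = 400$ they are common;
  the generator keeps them, and the test layer drops them with a warning
  (their score components are identically zero, so results for
  $\rho = 0$ are unaffected).

What a green simulation grid does **not** establish: the generator has
no realistic linkage-disequilibrium structure (AR-1 only), no
site-frequency-spectrum MAF distribution, no genotyping error or
missingness, and no case-control ascertainment.  Conclusions transfer to
real sequence data only at the level of the mechanism (outlier leverage
on score tests), not of absolute power numbers.

## Transforms in the experiment grid

With covariates the grid follows the two-step procedure used for the
transformation comparisons: regress $Y$ on $Z$ under the null, then
apply the inverse-normal transform to the residuals and test them
without covariates.  The natural-log transform applies to the raw trait
(it requires positivity, as with triglyceride levels) — log of centered
residuals is undefined, so the simulated transform comparisons use INV.
Winsorizing, by default, deliberately acts on raw trait values ignoring
covariates (the ad hoc practice being critiqued); the residual-based
variant sits behind `residual_based = TRUE`.

## Numerical choices and degenerate inputs

* Ties in resampling counts always count toward the null; no
  randomized tie-breaking.
* MAD = 0 (at least half the values identical) is flagged; robust
  scoring refuses to divide by it and says so, rather than silently
  falling back.
* Quadratic-form eigenvalues are clipped at zero below 1e-10 relative
  roundoff; an all-zero spectrum returns p = 1 with a warning.
* The Gaussian and robust engines share one resample draw per gene
  (one seed), so aSPU/aSPUr comparisons are paired.
* Per-cell seeds in the grids derive deterministically from the master
  seed and cell index, so any cell regenerates independently.
* VCF sites are oriented to the minor allele by sample frequency; a tie
  at 0.5 keeps ALT as the counted allele.  Missing genotypes impute to
  0 (non-carrier) with a warning.

## Known limitations

* The alternative robust scale built from an initial $\hat\beta_0$ (and
  Tukey-biweight loss) are deliberately out of scope, as is SKAT-O and
  any binary-trait GLM machinery.
* The Beta(1, 25) MAF-weight hook is provided but unvalidated against a
  reference implementation.
* aSPUr is conservative against genuinely large effect sizes (a large
  true effect on a rare variant is indistinguishable from a contaminated
  trait and gets clipped); it is a complement to aSPU, not a
  replacement.
* Under Cauchy errors our exact-permutation aSPUr holds size at ~0.05
  where the original report is conservative (~0.03); see the repository
  decision notes for measurements.
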