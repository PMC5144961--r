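---
title: "Methods: partitioning X-linked and autosomal genetic variance in lifespan and aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning X-linked and autosomal genetic variance in lifespan and aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: the
models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The design and the estimand

A hemiclone assay clones one haploid chromosome set — an X copy, or a
matched AII+AIII pair — identically across all individuals of a line, while
the genetic background is re-randomized in every individual. With lines
sampled at random from an outbred base population, the among-line variance
`V_L` of a trait estimates half the additive genetic variance carried by
the cloned set, with no dominance contribution (each background allele
meets the cloned haplotype in a random heterozygous combination). Hence the
conversion implemented in `additive_variance()`:

* `V_A = 2 V_L` for diploid cloned sets (autosomes, and the X measured in
  females);
* `V_A = V_L` for the X measured in males, where the cloned copy is the
  only copy (hemizygosity).

The default design (`design_config()`) is 40 lines per chromosome type,
both sexes, four replicate batches, and one vial of 50 flies per
line × sex × batch, with mortality scored every 2 days. That is 200 flies
per sex and line and 32,000 flies in total — the scale at which the
reference estimates shipped in `reference_estimates()` were obtained.

## Lifespan model

Individual lifespans are modelled as Gaussian,

```
y_ijkl = mu_sex + batch_{sex,k} + u_{line,sex} + w_vial + e
```

with (per chromosome type) a 2×2 unstructured cross-sex line covariance
matrix `G` (variances `V_LF`, `V_LM`, covariance `Cov_MF`), per-sex vial
variances, and per-sex residual variances. Vial and residual cross-sex
covariances are structurally zero: a vial houses one sex, a fly is one sex,
so those covariances are not defined by the data and are constrained to
zero rather than estimated. Treating the two sexes as separate response
traits in one model is what makes the intersexual correlation
`r_MF = Cov_MF / sqrt(V_LF V_LM)` directly estimable with a proper
posterior. The vial effect absorbs shared vial environment *and*
genotype-by-batch interaction, because there is a single vial per
line × batch — a deliberate confounding inherited from the design.

Batch fixed effects are sex-specific dummies for batches 2..B, centred by
subtracting their column means before crossing with the sex indicator
(`build_design()`), so the two intercepts estimate the sex-specific global
means rather than a reference batch. This matters downstream: the
per-sample `CV_A = sqrt(V_A)/mean` uses the intercept's posterior as the
mean.

### Gibbs sampler

All conditionals are conjugate for Gaussian responses, so the sampler
(`run_gibbs()`, compiled core) is a blocked Gibbs scheme with a fixed
update order: fixed effects; per-line bivariate effects; line
parameter-expansion scales; the working line covariance (inverse-Wishart);
vial effects, scales and variances; residual variances. The line and vial
terms use parameter expansion: the random effect is `diag(a)·eta` with
`eta ~ N(0, Psi)`, `Psi` inverse-Wishart with belief `nu_random = 2` and
identity scale, and expansion scales `a ~ N(0, 1e6)`. The implied prior on
`G = diag(a)·Psi·diag(a)` is the heavy-tailed scaled-F family that keeps
chains mixing when variances are near zero — the regime X-line female
variances actually occupy. Residual variances get a near-flat scaled
inverse chi-squared prior with `nu_residual = 0.002`. The reference
analysis states only the two belief parameters; the identity prior scale
and the `1e6` expansion variance are this package's declared defaults, and
a sensitivity harness (test suite) verifies that line-variance posteriors
move by less than one posterior SD across `nu ∈ {0.002, 2, 3}`.

Two implementation choices are worth flagging:

* **Sufficient statistics.** The sampler runs on per-vial statistics
  (mean, count, within-vial sum of squares) rather than individual flies.
  For this Gaussian model the reduction is exact — every conditional
  depends on the data only through those statistics — and it makes a
  30,000-iteration chain on a full 16,000-fly line type a matter of
  seconds. It also fixes the exchangeability contract: groups are ordered
  canonically by (line, sex, batch), so permuting input rows changes
  nothing, bit for bit, given the same seed.
* **One fly per vial is rejected** for the lifespan model: vial and
  residual variances are then confounded, and the fit refuses to run
  rather than return an unidentified decomposition.

Chain defaults (`chain_config()`) are a desk-scale 30,000 iterations,
5,000 burn-in, thinning 25 (1,000 retained samples);
`paper_scale_chain_config()` provides the production-scale
1,100,000/100,000/1,000. Convergence is checked with `gelman_rubin()`
(two or more chains required): the corrected potential scale reduction
factor with an F-based upper confidence limit, flagged above 1.05.

### REML and likelihood ratio tests

`reml_fit()` maximizes the restricted log-likelihood directly, on the same
vial-level statistics (vial means carry the line covariance plus a diagonal
`V_V + V_R/n` term; within-vial contrasts involve `V_R` only; the REML
adjustment uses the vial-level fixed-effect cross-product, which is exact
because all fixed effects are constant within vials). Traits are the up to
four sex × type combinations; cross-type line covariances are structurally
zero because a line is one type.

Numerical choices: log-variance and `atanh`-correlation parameterization
(every iterate is a valid covariance structure); moment starting values
that coincide with the balanced-design expected-mean-square estimators, so
on balanced data the optimizer merely confirms the closed-form answer
(the test suite asserts equality to machine precision there, and agreement
with `lme4` on univariate fits); `nlminb` with tight tolerances plus a
polish pass, since very tight tolerances can trip its false-convergence
heuristic on flat ridges.

Constraints are implemented by reparameterization — a constrained variance
is reconstructed from its source parameter, never penalized:
`zero_line` (a named line variance fixed at 0), `x_proportion` (the
X share of `V_A` in one sex fixed, e.g. at the euchromatin share 0.188 or
gene share 0.156), `va_ratio_mf_x` (the male:female X-linked `V_A` ratio
fixed, optionally on the mean-standardized CV² scale using observed sex
means as plug-ins), and `equal_rmf` (one shared correlation across types).
`lrt()` refers `2Δl` to `chi²_df`, the convention used for the reference
analysis; for variance components tested on the boundary this is
conservative, and the `0.5·chi²_0 + 0.5·chi²_1` mixture is available
behind `boundary_mixture = TRUE`. The package keeps `chi²_1` as the
default deliberately, to match the convention of the analysis it
re-implements; the calibration test confirms the resulting test is
conservative (empirical size below nominal) under a true null.

## Aging model

Mortality is Gompertz: hazard `mu(t) = alpha·exp(beta·t)`, survivorship
`S(t) = exp(-(alpha/beta)(exp(beta t) - 1))`, with the exponential limit at
`beta = 0` taken by a series expansion below `|beta| < 1e-8` to avoid 0/0.
`fit_gompertz()` maximizes the interval-censored likelihood
`sum_j d_j log[S(t_{j-1}) - S(t_j)] + c·log S(t_J)` per vial. The censoring
term is included even though cohorts of 50 flies essentially always die
out within the assay; it costs nothing and keeps truncated assays valid.

Numerical choices: optimization on `(log alpha, beta)` (positivity and
skew control) from a 3×3 multi-start grid anchored at the observed median
death age; a BFGS polish restart; standard errors from the observed
information, with the delta method for `alpha`. Convergence additionally
requires a curvature-scaled stationarity check — the expected
log-likelihood gain of one Newton step below 1e-3 — because a raw gradient
norm is scale-blind on the flat `beta` ridges of 50-fly cohorts. Schedules
whose deaths all fall in one census interval leave `beta` unidentifiable
and are returned flagged, not fitted. The age origin `t = 0` is the start
of the census clock; the absolute scale of `alpha` depends on that choice,
`beta` does not.

Because there is one death schedule per vial, aging is analysed in two
steps: per-vial `beta` estimates (reported as `beta × 100` to keep the
mixed-model variances well-conditioned) become the response of the same
multi-response model *without* the vial random effect — literally the same
code path with the vial flag off. A single-step nonlinear hierarchical
model is out of scope (the reference analysis attempted one and it did not
converge). The two-step approach discards the per-vial standard errors at
the second stage; estimation noise therefore appears as residual variance,
which is the correct interpretation under the model but means the
second-stage `V_R` is not pure biology.

The `log(alpha)`–`beta` correlation across vials
(`log_alpha_beta_correlation()`) uses Pearson correlation with a Fisher-z
interval, `alpha` log-transformed for skew. A caveat the test suite makes
explicit: the ML sampling errors of `(log alpha, beta)` are themselves
strongly negatively correlated along the likelihood ridge, so with 50-fly
cohorts the observed correlation mixes the biological trade-off with the
estimation geometry; only with very large cohorts does it isolate the
former. The generator's default generative correlation is −0.9.

## Derived statistics

`derive_stats()` applies every conversion per retained posterior sample —
`V_A`, `V_P = V_L + V_V + V_R` (no `V_V` for aging), `CV_A`, `r_MF` — and
only then summarizes, so a reported mean of a ratio is the mean of the
per-sample ratios. Plug-in values from posterior means are a different
quantity (Jensen's inequality) and are available separately through
`make_table1()`-style summaries; the two agree for linear quantities like
`V_P` and differ for ratios.

Cross-type contrasts (`cross_type_stats()`) — X-linkage proportion,
male:female `V_A` and `CV_A` ratios, the ratio-of-ratios
`(CV_AMX/CV_AFX)/(CV_AMA/CV_AFA)` (√2 expected under full dosage
compensation of a purely additive X), and `r_MF_X − r_MF_A` — link the two
independent model posteriors by one random permutation pairing
(`chain_difference()`), reporting the fraction of paired differences ≥ 0.
Ratio posteriors are right-skewed whenever female variance samples approach
zero; those quantities default to median/IQR summaries, and samples with
zero denominators are dropped and counted (a warning above 10%), never
clamped.

## Outlier vials

Vials of the screened sex (females by default) with mean lifespan strictly
below 51 days are flagged; ties at the threshold are kept. The threshold
is applied to pooled per-vial means across batches. A separation diagnostic
(days between the highest flagged and lowest unflagged vial) indicates
whether the low group is a detached mode, as an extrinsic insult (e.g.
disease in a vial) would produce, rather than a distribution tail. The
genetic-association check (`line_group_test()`) removes flagged vials,
recomputes line means, and runs a pooled-variance one-tailed t-test of
"lines without a flagged vial outlive lines with one" — pooled Student
rather than Welch, which is what yields integer degrees of freedom
(`t_38` for 40 lines). The pipeline reports results both with and without
removal.

## The synthetic-data generator

`simulate_lifespans()` draws exactly the lifespan model above: bivariate
normal line effects, Gaussian vial effects and residuals, fixed batch
offsets (defaults span about ±1.2 days, sum-to-zero within sex). Negative
Gaussian draws are truncated at 1 day and counted — the Gaussian model
admits them, real lifespans do not, and a positive floor keeps the
census-interval binning well defined. At the shipped parameter magnitudes
truncation is astronomically rare; it only bites in deliberately degenerate
test scenarios. `simulate_gompertz_cohort()` inverse-CDF samples death
ages and bins them on the census grid (half-open intervals `(t_{j-1},
t_j]`, censuses only at whole intervals, survivors past the last census
right-censored). `simulate_mortality_schedules()` adds per-line aging
variation: cross-sex bivariate `beta`, and `log alpha` conditionally
correlated with `beta` at −0.9 by default. `inject_outlier_vials()`
contaminates a fraction of target-sex vials with a fixed downward shift
(25 days by default), choosing vials independently of genotype — encoding
the verified null of the outlier screen — with a `genetic_outliers` switch
for power studies.

One master seed drives everything: `split_seed()` derives per-stage child
seeds deterministically (seed the RNG once with the master, draw distinct
31-bit integers), so stages are reproducible and decoupled.

What the generator does *not* emulate, and what passing tests therefore do
not establish about real data: the crossing scheme, balancer chromosomes
and recombination (lines are abstract draws from `G`); larval-density
standardization, mating-phase and anesthesia effects; non-Gaussian lifespan
shapes (real lifespan distributions are left-skewed — the Gaussian mixed
model is the analysis assumption, faithfully mirrored, not a claim about
flies); age-varying vial environments; and any correlation between lifespan
records and aging schedules beyond what the census binning of one dataset
induces. Parameter-recovery results show the estimators are correct under
the model's own assumptions at the assay's size — robustness to model
misspecification must come from elsewhere.

## Problem sizes and test design

The test suite runs at sizes chosen to separate signal from Monte-Carlo
noise while keeping a full run in minutes: moment checks at 1e5 draws
(3 MC SE bands), mixed-model coverage at the full single-type design
(40 lines × 2 sexes × 4 vials × 50 flies) over 20 replicate assays with
reduced chains (30k/5k/25), Gompertz recovery across 160 vials of 50,
LRT calibration over 500 null replicates, and REML–Gibbs concordance on a
150-line dataset where every component is well away from zero (5%
agreement band; posterior means and REML point estimates are different
estimators and agree only asymptotically). The degenerate cases —
zero-variance pipelines, single-interval schedules, one fly per vial,
perfect correlations — are asserted as exact behaviours, not tolerances.

## Known limitations

* The X:A comparison treats the fourth (dot) chromosome and the Y as
  negligible; the A-lines clone AII+AIII only.
* Epistasis between the cloned set and the background is absorbed into
  `V_L` and inflates `V_A` estimates slightly; the design cannot separate
  it.
* The two-step aging analysis propagates no first-stage uncertainty into
  the second stage (see above).
* `chi²_1` reference distributions for boundary variance tests are
  conservative; exact mixture weights for the multi-constraint tests are
  not implemented.
* REML standard errors are not reported; inference on REML fits goes
  through likelihood ratio tests, and interval summaries through the
  Bayesian fits.
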