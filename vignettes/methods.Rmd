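---
title: "Methods: two-cohort cord-blood methylation analysis with cordews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-cohort cord-blood methylation analysis with cordews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cordews` implements the analysis stack of a two-cohort epigenome-wide
association study (EWAS) of gestational diabetes mellitus (GDM) exposure in
fetal cord blood, measured on Illumina 450K-style methylation arrays. The
analysis object is the beta value — the methylation fraction
`beta = M / (M + U + offset)` at a CpG — and the scientific question is
whether exposed newborns (insulin-treated I-GDM, dietetically treated D-GDM)
differ from controls by small shifts (a few percentage points) at individual
CpGs, robustly across two independently collected cohorts.

The stack runs, in order:

1. **Probe QC** (`filter_probes`): removal of probes with a beadcount below 3
   or a detection p-value above 0.05 in any sample, then SNP-overlapping
   probes, then sex-chromosome probes. Attribution is to the first removing
   stage, so stage counts partition the input.
2. **Between-array normalization** (`dasen_normalize`): methylated and
   unmethylated intensities are background-aligned and quantile-normalized
   separately within probe design type (four strata).
3. **Within-sample type II correction** (`bmiq_correct`): a three-state
   beta-mixture quantile dilation mapping the compressed type II betas onto
   the type I mixture.
4. **Differential methylation** (`moderated_t_test`): per-cohort
   empirical-Bayes moderated t-tests on beta values for the I-GDM vs control
   contrast, with Benjamini-Hochberg (BH) adjustment.
5. **Meta-combination** (`combine_cohorts`): per-probe p-values of the two
   cohorts are combined through the order statistics of two independent
   uniform variables — first order `1 - (1 - min(pA, pB))^2` (sensitive),
   second order `max(pA, pB)^2` (robust: requires support from both
   cohorts). BH is applied to the combined p-values across all probes shared
   by both cohorts.
6. **Cell composition** (`estimate_cell_proportions`): constrained projection
   of each methylome onto cell-type reference profiles
   (`min ||b - Rw||^2, w >= 0, sum(w) <= 1`), with rank-test comparisons of
   compositions between groups.
7. **Targeted validation** (`mw_compare_cpgs`, `adjusted_effect_regression`,
   `neighbor_cpg_difference`): pyrosequencing-style per-CpG statistics —
   Mann-Whitney tests, OLS effect estimates adjusted for maternal BMI,
   gestational week and fetal sex, and the difference between neighboring
   CpGs treated as a derived phenotype.
8. **Cohort tables** (`build_characteristics_table`): baseline
   characteristics with rank tests for continuous rows, Fisher's exact test
   for 2x2 categorical rows and Pearson's chi-square for larger ones.

## Statistical assumptions

The moderated t assumes probe-wise residual variances exchangeable under a
scaled inverse-chi-square prior; its hyperparameters `d0` (prior degrees of
freedom) and `s0^2` (prior variance) are estimated by the log-variance moment
method: with `e_g = ln s2_g - digamma(d_g/2) + ln(d_g/2)`, `d0` solves
`trigamma(d0/2) = mean[(e_g - ebar)^2 m/(m-1) - trigamma(d_g/2)]`
(bisection on a log grid; infinite when the right side is non-positive), and
`s0^2 = exp(ebar + digamma(d0/2) - ln(d0/2))`. Note the homogeneous-variance
limit recovers the common variance only up to the factor
`(d/2)/exp(digamma(d/2))` (about 1.03 at d = 36) — an intrinsic small-sample
property of the log-scale estimator, shared by the standard empirical-Bayes
implementations.

The order-statistic combination assumes independent cohorts and per-cohort
p-values uniform under the null; both combined statistics are then exactly
uniform (they are the null CDFs of the minimum and maximum). Second-order
significance at combined threshold `c` is equivalent to both cohorts being
below `sqrt(c)`.

Tests are run on beta values rather than M-values, matching how effect sizes
are reported (percentage points of methylation); an M-value analysis is a
trivial transformation the user can apply upstream if preferred.
The per-cohort array model is the two-group contrast only; covariate
adjustment is deliberately the validation module's job
(`adjusted_effect_regression`), where the confounders are measured on the
same samples. Pairwise group models (all GDM vs control, I-GDM vs control,
D-GDM vs control) are used rather than one three-group model, keeping each
reported coefficient a two-group contrast.

# The synthetic-data generator

`simulate_cohort()` is first-class, tested code that defines the study
conditions the package is validated under:

* **Design.** Two cohorts sharing one probe set and one truth table:
  A with 18 controls and 20 I-GDM; B with 46 controls, 24 D-GDM and 24
  I-GDM. A targeted validation panel uses 56 controls, 64 D-GDM and 61
  I-GDM.
* **Baselines.** Probe means drawn from a three-component beta mixture
  (mostly unmethylated / hemimethylated / mostly methylated, weights
  0.40/0.15/0.45), reproducing the bimodal 450K beta distribution.
* **Within-group noise.** Per-sample betas are `Beta(m*phi, (1-m)*phi)` with
  precision `phi = 1200` by default, i.e. a within-group SD of roughly
  1-1.5 percentage points at intermediate methylation. The study data this
  emulates called thousands of sub-2-pp group differences significant at
  genome-wide FDR with 24 vs 46 samples, which is only possible at per-probe
  noise near this level; the default is chosen to reproduce that detection
  regime.
* **Effects.** A fraction (default 2%) of clean autosomal, non-SNP,
  non-discriminating probes with intermediate baselines receive effects of
  1-4.5 pp (random sign, flipped away from clipping bounds), added on the
  raw beta scale and clipped — matching how array effect sizes are reported.
  Effects are planted in the I-GDM group by default.
* **Asymmetric cohort power.** Effects are scaled per cohort
  (`cohort_effect_scale`, default A = 0.5, B = 1). This emulates a
  discovery/replication pair in which the smaller cohort carries only a
  weakly replicating share of the signal — the regime in which the sensitive
  first-order combination returns many more hits than the robust
  second-order one. With symmetric, fully shared effects the second-order
  statistic is the *more* powerful one probe-wise (`max(p,p)^2 = p^2 < 2p`),
  and the characteristic first >> second ordering disappears.
* **Type II bias.** Type II probes (70% of the array) are compressed toward
  0.5 by a fixed dilation `b' = 0.5 + (b - 0.5) * type2_bias`
  (default 0.8), giving BMIQ a well-defined target.
* **Cell mixtures.** Each sample is a Dirichlet mixture (concentration 5)
  over 6 cell-type profiles that differ at 200 discriminating probes by at
  least 0.5.
* **Side channels.** Beadcounts (`3 + Poisson(11)`) and detection p-values
  (`Beta(1, 2000)`) are generated directly with planted failure rates of
  2e-4 per cell, since the QC stage consumes only these channels.
* **Covariates.** Maternal BMI, gestational week, fetal sex, HbA1c (GDM
  groups only) and birth weight are drawn from group-dependent normal
  models; I-GDM mothers have higher BMI (29.9 vs 25.3 kg/m2) and earlier
  delivery (38.7 vs 39.5 weeks), so group contrasts are genuinely
  confounded. In the targeted panel, linear covariate effects on
  methylation can be switched on (`covariate_effects`) to exercise the
  adjusted regression; they default to zero so that planted group effects
  are exactly recoverable.
* **Panel noise.** Technical noise SD of 1.5 pp, matching typical
  replicate-to-replicate variability of bisulfite pyrosequencing (1-2 pp).

What the generator does **not** emulate: raw two-color fluorescence and IDAT
structure, batch/chip effects, spatially correlated probes, genetic
(mQTL) structure, and cell-type-specific disease effects. Passing recovery
tests therefore demonstrates the correctness and calibration of the
statistical machinery under the declared model, not robustness to artifacts
absent from that model.

# Numerical choices

* **Beta-mixture EM** (`fit_beta_mixture`): initialization by thresholding
  at 0.2/0.75 (falling back to three quantile centers when a group is
  empty, as happens for strongly compressed type II data), method-of-moments
  M-steps, convergence at relative log-likelihood change below 1e-4, at most
  100 iterations. Because the weighted method-of-moments update is not a
  strict likelihood ascent, an update that would decrease the log-likelihood
  is rejected and iteration stops — the reported trace is non-decreasing by
  construction. Data are clipped to `[1e-6, 1 - 1e-6]`; at least 50 values
  are required; an all-constant state errors out as degenerate.
* **BMIQ state boundaries** are posterior crossing points of adjacent fitted
  components (root-finding between component means, midpoint fallback), so
  state assignment is an interval rule and the full map is monotone;
  U/M states map by `qbeta(pbeta(.))` quantile matching and the
  hemimethylated interval by the linear dilation anchored at the transformed
  boundaries. Beta CDF/quantile evaluation uses the regularized incomplete
  beta function and its inverse as implemented in `pbeta`/`qbeta`
  (precision well beyond 1e-8).
* **dasen background step** aligns each sample's 1st percentile to the
  across-sample median of 1st percentiles before quantile normalization —
  a simplification that preserves the method's intent (background
  comparability between samples within each probe-type stratum) with a
  crisply testable definition. Negative values after alignment are clamped
  at zero after normalization, uniformly across samples.
* **Variance-prior bisection** runs 200 geometric bisection steps on
  `(1e-8, 5e5)` for `d0/2`; `d0` above 1e6 is reported as infinite and the
  t reference distribution degenerates to the normal.
* **Constrained projection**: Lawson-Hanson NNLS first; if the weights sum
  above `1 + 1e-8`, an exact active-set solve of the equality-constrained
  problem (KKT system with dual-feasibility checks) replaces it. Degenerate
  probes (t = 0 and delta = 0) report p = 1.
* **Mann-Whitney**: exact enumeration of all group assignments when both
  groups have at most 8 observations and no ties; otherwise the normal
  approximation with tie-corrected variance and no continuity correction,
  for reproducible small-sample behavior. All-tied data report p = 1.
* **Seeding**: `run_pipeline` fans a single seed out to per-stage sub-seeds
  by a fixed counter scheme (`seed + 10 * stage_index`), so a stage can be
  re-run in isolation with identical output.

# Problem sizes

The test-suite and acceptance computations use desk-scale versions of the
study design: 2,000-10,000 probes (the real array has ~485,000), the
original sample sizes (38 and 94 arrays, 181 panel samples), 3-10 simulation
seeds per property, and 1e5 draws for null-uniformity checks. These sizes
are the package's own calibration choices: large enough that empirical
rates (type-I error, false-discovery proportion, detection of >= 4 pp
effects) are stable at the asserted tolerances, small enough to run
anywhere. Genome-scale probe counts change only multiplicity, which BH and
the combination handle identically at any scale.

# Known limitations

* Counts reported at genome scale by the emulated study (for example the
  sizes of its significant CpG lists) are not reproducible at desk scale;
  the package validates the machinery by planted-truth recovery instead.
* The two-sided Fisher exact p and the Pearson chi-square p agree only
  asymptotically; at expected cell counts near 80 they can differ by up to
  ~0.1, which the tests assert as the verified behavior.
* Reference-based deconvolution is only as good as the supplied reference;
  the bundled reference generator is synthetic and carries no claim about
  real cord-blood cell types.
* The adjusted regression treats gestational week as linear and fetal sex
  as a 0/1 covariate; nonlinear gestational-age effects are out of scope.
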