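---
title: "Separating direct and adult-mediated effects of early-life body size"
author: "lifecourseMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating direct and adult-mediated effects of early-life body size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecourseMR)
```

## The question and the causal model

People who were larger than average as children tend to have higher disease
risk as adults. Is that because childhood adiposity harms the body directly,
with consequences that persist whatever happens later — or only because
larger children usually become larger adults, and adult adiposity does the
damage? The distinction matters: if the effect is entirely mediated through
adult body size, it is modifiable later in life.

`lifecourseMR` implements a two-sample Mendelian randomisation (MR)
framework for this question. Genetic variants associated with body size act
as instrumental variables: because genotypes are fixed at conception, their
associations with disease are not confounded by lifestyle, and reverse
causation is excluded. Writing $E$ for the early-life body-size liability,
$A$ for adult body size, $U$ for a shared confounder and $Y$ for the
outcome's linear predictor, the simulated world follows the linear path
model

$$
E = G\beta_E + \lambda_E U + \varepsilon_E, \qquad
A = \theta_{EA} E + G\beta_A + \lambda_A U + \varepsilon_A, \qquad
Y = \theta_E E + \theta_A A + \lambda_Y U + \varepsilon_Y,
$$

with independent unit-variance noise terms. Three canonical scenarios
correspond to settings of the two outcome paths: *fully mediated*
($\theta_E = 0$, $\theta_A \neq 0$), *direct only* ($\theta_E \neq 0$,
$\theta_A = 0$), and *both*. The total causal effect of $E$ is
$\theta_E + \theta_{EA}\theta_A$; the indirect (adult-mediated) effect is
the product $\theta_{EA}\theta_A$, i.e. total minus direct.

Univariable MR with early-life instruments estimates the **total** effect.
Multivariable MR (MVMR), regressing per-variant outcome associations
jointly on early-life and adult association columns, estimates each
exposure's **direct** effect conditional on the other. The difference is
the indirect effect, and the pattern of the three identifies the scenario.

## What the generator emulates — and what it does not

`scenario_spec()` + `simulate_panel()` + `simulate_cohort()` produce
individual-level two-sample data with the statistical structure the
analysis assumes:

* **Genotypes.** Biallelic variants with MAF uniform on `maf_range`
  (default 0.1–0.45), in LD blocks: each haplotype is a thresholded
  equicorrelated Gaussian (`ld_rho` on the latent scale), two haplotypes
  per individual. Dichotomisation attenuates the realised dosage-scale
  correlation below `ld_rho` (for `ld_rho = 0.8` at MAF 0.3 the dosage
  correlation is ≈ 0.65); tests therefore compare the realised LD against
  a Monte-Carlo oracle of the same latent model rather than against
  `ld_rho` itself. With `ld_block_size = 1` the model reduces exactly to a
  binomial dosage draw. Effect alleles are minor alleles, and palindromic
  (A/T, G/C) pairs are excluded unless requested, so harmonization of
  simulated data is exact by construction.
* **Architecture.** Disjoint sets of early-only and adult-only variants
  (defaults 30 + 30 of 100, per-allele effects $N(0, 0.15^2)$ in
  latent-SD units), an optional shared set, and null variants. A
  per-allele effect of ~0.15 SD is deliberately generous relative to real
  anthropometric GWAS hits; at the default sample size of 20 000 it yields
  instruments with mean F in the hundreds, so the framework is evaluated
  in the strong-instrument regime it assumes.
* **Measures.** The early-life measure is a 3-category variable
  (thinner / about average / plumper) obtained by a quantile cut of the
  early latent at `category_proportions` (default tertiles — the real
  survey proportions are not public, and the choice is exposed in
  configuration). The adult measure is kept on its measured continuous
  scale by default, and `adult_category` applies the *same* proportions
  to the adult latent for analyses that want both measures categorical.
* **Recall error.** `apply_misclassification()` redraws the *reported*
  early category from a row-stochastic confusion matrix
  (`symmetric_confusion(0.1)` by default: 10% of each row's mass spills
  to adjacent categories). In differential mode the row is exponentially
  tilted towards higher categories in proportion to the individual's
  mean-centred adult latent: the log-odds of reporting one category
  higher increase by `adult_dependence_slope` (default 0.4 in the study
  cells) per latent-SD of adult size. Across the adult-latent
  interquartile range this moves over-reporting by roughly ±10
  percentage points. True categories are retained for oracle comparisons.
* **Covariates and controls.** Age, sex and month of birth are drawn
  independently of everything (they exercise the adjustment machinery
  without creating confounding); age at menarche depends on the early
  latent only, encoding the fact that adult body size cannot influence
  the timing of puberty — the negative control.

Passing tests on these data show that the pipeline recovers what it is
designed to recover under its own assumptions. They do not speak to
population stratification, relatedness, assortative mating, dynastic
effects, imputation error, or non-linear mediation — none of which are
simulated.

## The analysis chain

`run_replicate()` executes the full chain once: scan each exposure in the
exposure sample (`gwas_scan()`: per-variant least squares with covariate
adjustment, the 0/1/2 category coding assuming equal per-step effects, and
month-of-birth adjustment for the early scan), scan the outcome in an
independent outcome sample, select instruments by greedy LD clumping
(`ld_clump()`, p < 5×10⁻⁸, r² < 0.001, ties broken by variant id), form
the jointly re-clumped union across exposures
(`cross_exposure_instrument_set()`), align alleles (`harmonize()`), and fit
`mr_ivw()`, `mvmr_fit()` and `decompose_effects()`.

Key estimator conventions:

* **IVW** is the fixed-effect inverse-variance weighting of per-variant
  Wald ratios — equivalently weighted least squares of outcome betas on
  exposure betas through the origin with weights $1/\mathrm{se}_y^2$; the
  first-order Wald standard error ignores exposure uncertainty,
  consistently with those weights. Cochran's Q (df = variants − 1) and the
  mean instrument F accompany every fit. A multiplicative random-effects
  option inflates the standard error by $\sqrt{\max(1, Q/\mathrm{df})}$.
* **MVMR** solves the weighted normal equations with no intercept;
  fixed-effect standard errors come from $(X'WX)^{-1}$, and the same
  random-effects option exists. With one exposure the fit equals IVW to
  machine precision (asserted in tests). Conditional instrument strength
  regresses one exposure's betas on the others' (no intercept, that
  exposure's inverse-variance weights) and divides the weighted residual
  sum of squares by (variants − exposures + 1): orthogonal exposure
  columns recover the marginal mean F, duplicated columns give 0.
* **MR-Egger** orients exposure betas non-negative, fits with an
  intercept, and reports the intercept as the directional-pleiotropy
  test.
* **Decomposition.** Indirect = total − direct with the independence
  approximation for its standard error (flagged approximate — the two
  estimates share instruments and data, so this overstates uncertainty; a
  bootstrap is not possible on summary data). Scenario labels are a
  reporting heuristic: *mediated* when the direct CI covers 0 while the
  total CI excludes it; *direct only* when |indirect| < 20% of |total|
  with overlapping CIs; *both* otherwise.
* **Stacked interaction scan.** Each individual contributes their early
  and adult category as two rows; the variant × time coefficient (time
  coded 0 = early, 1 = adult) is the difference between the adult and
  early per-allele effects, with cluster-robust (by individual) standard
  errors because the two rows are correlated. Variants significant after
  Bonferroni correction over the tested set are flagged `stronger-early`
  or `stronger-adult` by comparing effect magnitudes.

## Design choices in the validation studies

The package validates itself with simulation studies (the test suite and
`scripts/acceptance.R` run scaled versions of the same studies; the
problem sizes there — e.g. 100-variant panels, samples of 20 000, tens to
hundreds of replicates — are the package's chosen desk-scale conditions).
Three choices deserve explanation because the design was genuinely open:

* **Where instruments are discovered.** When the exposure sample itself
  provides both the selection p-values and the instrument effect
  estimates — as when a single large GWAS serves both purposes — the
  selected betas are inflated (winner's curse), which attenuates MR
  estimates downstream (≈ −0.01 on a direct effect of 0.5 at the default
  architecture). `run_replicate(selection = "independent-sample")`
  discovers instruments in a third simulated sample instead. The
  *parameter-recovery* and *negative-control* studies use this mode
  because they characterise the estimators, not the selection design; the
  end-to-end pipeline default remains in-sample selection, which is what
  an analyst with one exposure GWAS actually does.
* **Which standard errors are checked for coverage.** The fixed-effect
  standard errors match the published convention and are the package
  default. But exposure-beta sampling error adds real dispersion beyond
  the $1/\mathrm{se}_y^2$ weights, and fixed-effect coverage sits near
  87–88% under the simulation's conditions whatever the instrument
  strength. The recovery studies therefore assess coverage with the
  multiplicative random-effects errors, which restore ≈ 93–95% coverage;
  this is exactly the situation the random-effects option exists for.
* **Estimator-comparison resolution.** The negative control demands that
  the early direct effect equal its univariable total. Summary-data MVMR
  carries a finite-sample offset between those two estimators of order
  $\mathrm{se}_x^2/\mathrm{var}(\beta_x)$ — under 1% of the effect here.
  The comparison is therefore made at the resolution of the estimates'
  own standard errors (and a 5%-of-total bound), not at the
  ever-shrinking standard error of a Monte-Carlo mean, which would reject
  any systematic sub-percent offset given enough replicates.
* **The misclassification study's architecture.** The study grid
  (`default_study_cells()`) uses a stronger architecture (per-allele SD
  0.25) than the generator default. The study's verdicts are "bias beyond
  3 Monte-Carlo standard errors" decisions; for those flags to be
  attributable to the misclassification mechanism, the nuisance
  finite-sample biases above must sit well below the detection threshold
  while the differential-misclassification bias (≈ ∓0.02 here, and
  independent of instrument strength) sits well above it.

## The misclassification study

`run_cell()`/`run_grid()` rerun the whole pipeline over a grid of
(scenario × misclassification model) cells — by default the 2 × 2 of
(differential?, early effect?) plus a clean cell and an
opposite-direction-early-effect cell, 20 000 individuals per sample.
Because the early exposure is scanned on the reported *category* scale,
its estimands are category-scale: the path coefficients divided by the
category/latent slope $\lambda$ (the derivative, in the Stein sense, of
the expected category with respect to the latent), which `run_cell()`
measures on a 200 000-person auxiliary cohort. The adult exposure stays on
its measured continuous scale, so its estimand is exactly
$\theta_A$ — which is what makes the headline unbiasedness claims
testable. `summarize_directions()` then reports the truth table: early
instrument strength is attenuated by misclassification; the adult direct
effect is unbiased wherever the early effect is absent, whatever the
error mode; bias in the adult effect appears only under *differential*
misclassification combined with an early effect, and its sign flips with
the direction of the early effect relative to the adult one — masking the
adult effect when the two act in the same direction.

## Numerical and degenerate-input conventions

Two-sided p-values use the normal approximation (samples are always
≫ 100) and are floored at the smallest positive double. A constant
genotype column yields beta 0, infinite standard error, p-value 1 and a
degenerate flag rather than an error. Clumping treats an undefined
correlation (constant dosage) as no LD. Equal p-values clump in variant-id
order. Category cuts use sample quantiles, so configured proportions are
matched up to sampling error. The harmonizer drops palindromic variants
with effect-allele frequency in [0.42, 0.58] (a conventional window,
exposed in configuration) and aligns the rest by minor-allele agreement;
variants missing from the outcome are excluded rather than proxied — no
LD-proxy lookup, no strand inference.

## Known limitations

Binary outcomes use a logistic model; because odds ratios do not collapse
over the mediator, exact path-product recovery is impossible on the
log-odds scale, and binary runs are checked for direction and
null-coverage only — the quantitative recovery studies use the continuous
outcome. The indirect-effect standard error is approximate (see above).
The conditional F statistic follows the construction documented here and
is validated by its limiting properties, not against any published
variant of the formula. Simulated individuals are unrelated and
unstratified by design, so per-variant least squares is the correct scan
model; mixed-model association is out of scope.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- load_config(overrides = list(
  seed = 3, output_dir = tempfile("mr_run"),
  scenario = list(beta_early_direct = 0, beta_adult_direct = 0.5),
  samples = list(n_exposure = 10000, n_outcome = 10000)))
dec <- run_pipeline(cfg)   # simulate, scan, clump, harmonize, MR, MVMR
print(dec)                 # decomposition + scenario label ("mediated")
```

Every stage writes plain TSV files plus the resolved configuration under
`output_dir`, and each stage can be rerun from the previous stage's
outputs (`cmd_simulate()` … `cmd_study()`, or the
`inst/cli/lifecourse-mr.R` entry point with the same subcommands).
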