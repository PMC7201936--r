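#' Specify a causal simulation scenario
#'
#' A `scenario_spec` parameterises the causal diagram linking genotypes,
#' early-life body size, adult body size, a shared confounder and a disease
#' outcome. The three canonical life-course scenarios are obtained by setting
#' the two exposure-to-outcome paths: an *indirect only* (fully mediated)
#' scenario has `beta_early_direct = 0` with non-zero `beta_early_to_adult`
#' and `beta_adult_direct`; a *direct only* scenario has a non-zero
#' `beta_early_direct` with `beta_adult_direct = 0`; and setting both paths
#' non-zero gives the mixed scenario. Age at menarche is modelled as a
#' downstream trait of the early latent only, since adult body size cannot
#' influence the timing of puberty.
#'
#' @param n_variants Number of biallelic variants in the panel.
#' @param maf_range Length-2 interval in (0, 0.5) for minor-allele
#'   frequencies, drawn uniformly per variant.
#' @param ld_block_size Number of adjacent variants per LD block; 1 gives
#'   independent variants.
#' @param ld_rho Latent-scale equicorrelation within an LD block, in
#'   `[0, 1)`. Haplotypes are thresholded Gaussians, so the realised
#'   dosage-scale correlation is somewhat attenuated relative to `ld_rho`.
#' @param n_early_variants,n_adult_variants,n_shared_variants Counts of
#'   variants with per-allele effects on the early latent trait only, the
#'   adult latent trait only, or both. The remainder of the panel is null.
#' @param effect_size_sd_early,effect_size_sd_adult Standard deviations of
#'   the per-allele effects (on the latent-trait scale, residual SD 1).
#' @param beta_early_to_adult Path coefficient from the early latent to the
#'   adult latent (the mediation arrow).
#' @param beta_early_direct,beta_adult_direct Exposure-to-outcome path
#'   coefficients on the outcome linear predictor.
#' @param outcome_model `"continuous"` (linear, unit residual SD) or
#'   `"binary-logistic"`.
#' @param baseline_prevalence Baseline outcome probability (binary model
#'   only), applied on the logit scale at a linear predictor of zero.
#' @param confounder_sd SD of the shared confounder.
#' @param confounder_loading_early,confounder_loading_adult,confounder_loading_outcome
#'   Loadings of the shared confounder on the two latent traits and the
#'   outcome linear predictor.
#' @param menarche_beta_early Path coefficient from the early latent to age
#'   at menarche (negative-control trait; adult size has no path to it).
#' @param category_proportions Three probabilities summing to 1: the marginal
#'   proportions of the thinner / average / plumper categories. The adult
#'   measure is categorised with the same proportions.
#' @param palindromic_alleles If `TRUE`, A/T and G/C allele pairs may be
#'   generated (to exercise the harmonization palindrome policy); disabled
#'   by default so harmonization of simulated data is exact.
#' @param seed Integer RNG seed; mandatory for reproducible panels/cohorts.
#'
#' @return An object of class `scenario_spec` (a validated named list).
#' @seealso [simulate_panel()], [simulate_cohort()], [misclass_model()]
#' @examples
#' spec <- scenario_spec(n_variants = 50, n_early_variants = 10,
#'                       n_adult_variants = 10, seed = 1)
#' spec$beta_early_direct
#' @export
scenario_spec <- function(n_variants = 100L,
                          maf_range = c(0.1, 0.45),
                          ld_block_size = 1L,
                          ld_rho = 0,
                          n_early_variants = 30L,
                          n_adult_variants = 30L,
                          n_shared_variants = 0L,
                          effect_size_sd_early = 0.15,
                          effect_size_sd_adult = 0.15,
                          beta_early_to_adult = 0.6,
                          beta_early_direct = 0,
                          beta_adult_direct = 0.5,
                          outcome_model = c("continuous", "binary-logistic"),
                          baseline_prevalence = 0.1,
                          confounder_sd = 1,
                          confounder_loading_early = 0.3,
                          confounder_loading_adult = 0.3,
                          confounder_loading_outcome = 0.3,
                          menarche_beta_early = -0.5,
                          category_proportions = c(1, 1, 1) / 3,
                          palindromic_alleles = FALSE,
                          seed = 1L) {
  outcome_model <- match.arg(outcome_model)
  n_variants <- check_count(n_variants, "n_variants", min = 1L)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1] > maf_range[2])
    config_error("field 'maf_range' must be an increasing length-2 interval")
  check_number(maf_range[1], "maf_range", 0, 0.5, open_lower = TRUE, open_upper = TRUE)
  check_number(maf_range[2], "maf_range", 0, 0.5, open_lower = TRUE, open_upper = TRUE)
  ld_block_size <- check_count(ld_block_size, "ld_block_size", min = 1L)
  ld_rho <- check_number(ld_rho, "ld_rho", 0, 1, open_upper = TRUE)
  n_early_variants <- check_count(n_early_variants, "n_early_variants")
  n_adult_variants <- check_count(n_adult_variants, "n_adult_variants")
  n_shared_variants <- check_count(n_shared_variants, "n_shared_variants")
  if (n_early_variants + n_adult_variants + n_shared_variants > n_variants)
    config_error(paste0("fields 'n_early_variants'+'n_adult_variants'+",
                        "'n_shared_variants' exceed 'n_variants' (%d > %d)"),
                 n_early_variants + n_adult_variants + n_shared_variants,
                 n_variants)
  if (!is.numeric(category_proportions) || length(category_proportions) != 3L ||
      any(category_proportions <= 0) ||
      abs(sum(category_proportions) - 1) > 1e-12)
    config_error("field 'category_proportions' must be 3 positive numbers summing to 1")
  spec <- list(
    n_variants = n_variants,
    maf_range = as.numeric(maf_range),
    ld_block_size = ld_block_size,
    ld_rho = ld_rho,
    n_early_variants = n_early_variants,
    n_adult_variants = n_adult_variants,
    n_shared_variants = n_shared_variants,
    effect_size_sd_early = check_number(effect_size_sd_early, "effect_size_sd_early", 0),
    effect_size_sd_adult = check_number(effect_size_sd_adult, "effect_size_sd_adult", 0),
    beta_early_to_adult = check_number(beta_early_to_adult, "beta_early_to_adult"),
    beta_early_direct = check_number(beta_early_direct, "beta_early_direct"),
    beta_adult_direct = check_number(beta_adult_direct, "beta_adult_direct"),
    outcome_model = outcome_model,
    baseline_prevalence = check_number(baseline_prevalence, "baseline_prevalence",
                                       0, 1, open_lower = TRUE, open_upper = TRUE),
    confounder_sd = check_number(confounder_sd, "confounder_sd", 0),
    confounder_loading_early = check_number(confounder_loading_early, "confounder_loading_early"),
    confounder_loading_adult = check_number(confounder_loading_adult, "confounder_loading_adult"),
    confounder_loading_outcome = check_number(confounder_loading_outcome, "confounder_loading_outcome"),
    menarche_beta_early = check_number(menarche_beta_early, "menarche_beta_early"),
    category_proportions = as.numeric(category_proportions),
    palindromic_alleles = isTRUE(palindromic_alleles),
    seed = check_count(seed, "seed")
  )
  class(spec) <- "scenario_spec"
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Life-course simulation scenario\n")
  cat(sprintf("  variants: %d (early %d, adult %d, shared %d, null %d); LD blocks of %d, rho=%.2f\n",
              x$n_variants, x$n_early_variants, x$n_adult_variants,
              x$n_shared_variants,
              x$n_variants - x$n_early_variants - x$n_adult_variants - x$n_shared_variants,
              x$ld_block_size, x$ld_rho))
  cat(sprintf("  paths: early->adult %.3g; early->outcome %.3g; adult->outcome %.3g; early->menarche %.3g\n",
              x$beta_early_to_adult, x$beta_early_direct,
              x$beta_adult_direct, x$menarche_beta_early))
  cat(sprintf("  outcome model: %s; seed %d\n", x$outcome_model, x$seed))
  invisible(x)
}

#' Specify a misclassification model for the early-life measure
#'
#' Models self-report error in the recalled early-life body-size category.
#' `"nondifferential"` misclassification draws the reported category from a
#' fixed row-stochastic confusion matrix given the true category.
#' `"differential-on-adult"` additionally tilts each confusion row towards
#' higher reported categories as the individual's actual adult (continuous)
#' body size increases: the probability of reporting category k is
#' proportional to `confusion[true+1, k+1] * exp(slope * k * a)` where `a`
#' is the mean-centred adult latent trait. Differential mode therefore
#' requires a non-degenerate confusion matrix (an identity row cannot be
#' tilted).
#'
#' @param mode One of `"none"`, `"nondifferential"`, `"differential-on-adult"`.
#' @param confusion 3x3 row-stochastic matrix, rows = true category 0..2,
#'   columns = reported category 0..2. Defaults to the identity for
#'   `mode = "none"` and to `symmetric_confusion(0.1)` otherwise.
#' @param adult_dependence_slope Per-unit-of-adult-latent shift in the
#'   log-odds of reporting one category higher (differential mode only).
#' @return An object of class `misclass_model`.
#' @examples
#' misclass_model("nondifferential", symmetric_confusion(0.1))
#' @export
misclass_model <- function(mode = c("none", "nondifferential", "differential-on-adult"),
                           confusion = NULL,
                           adult_dependence_slope = 0) {
  mode <- match.arg(mode)
  if (is.null(confusion))
    confusion <- if (mode == "none") diag(3) else symmetric_confusion(0.1)
  confusion <- as.matrix(confusion)
  if (!is.numeric(confusion) || any(dim(confusion) != c(3L, 3L)) ||
      any(confusion < 0))
    input_error("confusion must be a non-negative 3x3 matrix")
  if (any(abs(rowSums(confusion) - 1) > 1e-12))
    input_error("confusion matrix rows must each sum to 1 (got %s)",
                paste(format(rowSums(confusion)), collapse = ", "))
  if (mode == "none" && any(abs(confusion - diag(3)) > 1e-12))
    input_error("mode 'none' requires an identity confusion matrix")
  adult_dependence_slope <- check_number(adult_dependence_slope, "adult_dependence_slope")
  if (mode != "differential-on-adult" && adult_dependence_slope != 0)
    input_error("adult_dependence_slope is only meaningful in differential-on-adult mode")
  structure(list(mode = mode, confusion = unname(confusion),
                 adult_dependence_slope = adult_dependence_slope),
            class = "misclass_model")
}

#' Symmetric three-category confusion matrix
#'
#' Spills a fraction `spill` of each true category's probability mass onto
#' the adjacent categories (split evenly for the middle category).
#'
#' @param spill Total off-diagonal probability per row, in `[0, 1)`.
#' @return A 3x3 row-stochastic matrix.
#' @export
symmetric_confusion <- function(spill = 0.1) {
  spill <- check_number(spill, "spill", 0, 1, open_upper = TRUE)
  matrix(c(1 - spill, spill,       0,
           spill / 2, 1 - spill,   spill / 2,
           0,         spill,       1 - spill),
         nrow = 3, byrow = TRUE)
}

#' @export
print.misclass_model <- function(x, ...) {
  cat(sprintf("Misclassification model: %s", x$mode))
  if (x$mode == "differential-on-adult")
    cat(sprintf(" (adult-dependence slope %.3g)", x$adult_dependence_slope))
  cat("\nConfusion matrix (rows = true category):\n")
  print(round(x$confusion, 4))
  invisible(x)
}
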