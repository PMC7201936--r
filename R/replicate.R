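#' One full two-sample MR replicate on simulated data
#'
#' Runs the complete analysis chain on freshly simulated data: draw a
#' variant panel and two independent cohorts (exposure and outcome
#' samples), optionally misclassify the exposure sample's early-life
#' measure, scan both exposures in the exposure sample and the outcome in
#' the outcome sample, clump each exposure's results, form the jointly
#' re-clumped cross-exposure instrument set, harmonize, and fit the
#' univariable (total, early exposure) and multivariable (direct) models
#' with the effect decomposition.
#'
#' @param spec A [scenario_spec()]; its seed is overridden by `seed`.
#' @param seed Integer seed for this replicate (panel, both cohorts and the
#'   misclassification draw derive from it).
#' @param n_exposure,n_outcome Sample sizes of the two samples.
#' @param mis Optional [misclass_model()] applied to the exposure sample's
#'   early measure.
#' @param exposure_phenotypes Named character vector mapping exposure
#'   labels to phenotype columns scanned in the exposure sample. The
#'   default scans the (possibly misclassified) reported early category and
#'   the continuous adult trait.
#' @param outcome_phenotype Outcome column scanned in the outcome sample
#'   (`"outcome"` or `"menarche"`).
#' @param covariates Named list of covariate sets; entries `early`,
#'   `adult`, `outcome`.
#' @param p_threshold,r2_threshold Instrument selection thresholds
#'   (genome-wide significance and near-independence by default).
#' @param selection Where instruments are discovered: in the exposure
#'   sample itself (default; mirrors a design where one GWAS provides both
#'   the selection p-values and the exposure effect estimates, and so
#'   carries winner's-curse selection bias), or in a third simulated
#'   `"independent-sample"` of the same size, which isolates the
#'   estimators' own properties. Exposure effect estimates always come
#'   from the exposure sample.
#' @param random_effects Use multiplicative random-effects standard errors
#'   (se inflated by `sqrt(max(1, Q/df))`) in both fits; appropriate when
#'   exposure-beta sampling error adds overdispersion beyond the
#'   outcome-se weights.
#' @param outcome_scan_model `"linear"` or `"logistic"`; defaults to
#'   logistic for a binary-logistic scenario outcome (ignored for the
#'   menarche outcome).
#' @return List with elements `total_early` (univariable `mr_fit`), `mvmr`
#'   (`mvmr_fit`), `decomposition`, `mean_f_early` (mean F of the clumped
#'   early instruments), `instruments` (the joint `sumstats`),
#'   `n_instruments_early`, `n_instruments_joint`, and the harmonized sets
#'   `h_early`, `h_joint`.
#'
#'   If instrument selection leaves too few variants for estimation, an
#'   error of class `lifecourseMR_too_few_instruments` is raised (the study
#'   grid catches it and excludes the replicate).
#' @export
run_replicate <- function(spec, seed = spec$seed,
                          n_exposure = 20000L, n_outcome = 20000L,
                          mis = NULL,
                          exposure_phenotypes = c(early = "early_reported",
                                                  adult = "adult_latent"),
                          outcome_phenotype = "outcome",
                          covariates = list(
                            early = c("age", "sex", "month_of_birth"),
                            adult = c("age", "sex"),
                            outcome = c("age", "sex")),
                          p_threshold = 5e-8, r2_threshold = 0.001,
                          selection = c("exposure-sample", "independent-sample"),
                          random_effects = FALSE,
                          outcome_scan_model = NULL) {
  selection <- match.arg(selection)
  spec$seed <- check_count(seed, "seed")
  panel <- simulate_panel(spec)
  exposure_cohort <- simulate_cohort(panel, spec, n_exposure, "exposure")
  outcome_cohort <- simulate_cohort(panel, spec, n_outcome, "outcome")
  if (!is.null(mis) && mis$mode != "none")
    exposure_cohort <- apply_misclassification(exposure_cohort, mis)

  labels <- names(exposure_phenotypes)
  scan_exposures <- function(cohort) {
    out <- lapply(seq_along(exposure_phenotypes), function(i) {
      covs <- covariates[[labels[i]]]
      if (is.null(covs)) covs <- c("age", "sex")
      gwas_scan(cohort, exposure_phenotypes[[i]], covs)
    })
    names(out) <- labels
    out
  }
  stats_x <- scan_exposures(exposure_cohort)
  if (is.null(outcome_scan_model))
    outcome_scan_model <- if (outcome_phenotype == "outcome" &&
                              spec$outcome_model == "binary-logistic")
      "logistic" else "linear"
  stats_y <- gwas_scan(outcome_cohort, outcome_phenotype, covariates$outcome,
                  model = outcome_scan_model)

  # instrument discovery: in the exposure sample itself (as when one GWAS
  # provides both selection and effect estimates) or in a third,
  # independent discovery sample (removes winner's-curse selection bias)
  if (selection == "independent-sample") {
    discovery_cohort <- simulate_cohort(panel, spec, n_exposure, "exposure",
                                        seed = spec$seed + 3L)
    if (!is.null(mis) && mis$mode != "none")
      discovery_cohort <- apply_misclassification(discovery_cohort, mis)
    sel_stats <- scan_exposures(discovery_cohort)
    reference <- discovery_cohort
  } else {
    sel_stats <- stats_x
    reference <- exposure_cohort
  }
  clumped_sel <- lapply(sel_stats, ld_clump, reference = reference,
                        p_threshold = p_threshold, r2_threshold = r2_threshold)
  joint <- cross_exposure_instrument_set(clumped_sel[[1]], clumped_sel[[2]],
                                         reference,
                                         p_threshold = p_threshold,
                                         r2_threshold = r2_threshold)
  # instrument effect estimates always come from the exposure sample
  clumped <- lapply(labels, function(l)
    subset_sumstats(stats_x[[l]], clumped_sel[[l]]$SNP))
  names(clumped) <- labels
  n_early <- nrow(clumped[[1]])
  if (n_early < 2L || nrow(joint) <= length(labels))
    stopf("too few instruments after clumping (early %d, joint %d)",
          n_early, nrow(joint), class = "lifecourseMR_too_few_instruments")

  h_joint <- harmonize(lapply(stats_x, subset_sumstats, snps = joint$SNP),
                       stats_y)
  h_early <- harmonize(lapply(stats_x[1], subset_sumstats,
                              snps = clumped[[1]]$SNP), stats_y)
  total_early <- mr_ivw(h_early, exposure = labels[1],
                        random_effects = random_effects)
  fit <- mvmr_fit(h_joint, random_effects = random_effects)
  dec <- decompose_effects(total_early, fit, exposure = labels[1])
  list(total_early = total_early, mvmr = fit, decomposition = dec,
       mean_f_early = mean_f(clumped[[1]]),
       instruments = joint,
       n_instruments_early = n_early,
       n_instruments_joint = nrow(joint),
       h_early = h_early, h_joint = h_joint)
}
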