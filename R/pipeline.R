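#' Default run configuration
#'
#' Every exposed design decision has a documented key; unknown keys in a
#' user config are rejected. The instrument-selection defaults are
#' genome-wide significance (p < 5e-8) and near-independence (r² < 0.001).
#' An annotated example config ships at
#' `system.file("extdata", "example_config.yaml", package = "lifecourseMR")`.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "lifecourseMR_run",
    scenario = unclass(scenario_spec()),
    misclassification = list(mode = "none", spill = 0.1,
                             adult_dependence_slope = 0),
    samples = list(n_exposure = 20000L, n_outcome = 20000L),
    scan = list(early_phenotype = "early_reported",
                adult_phenotype = "adult_latent",
                outcome_phenotype = "outcome",
                early_covariates = c("age", "sex", "month_of_birth"),
                adult_covariates = c("age", "sex"),
                outcome_covariates = c("age", "sex")),
    clump = list(p_threshold = 5e-8, r2_threshold = 0.001),
    harmonize = list(palindrome_policy = "frequency",
                     palindrome_window = c(0.42, 0.58)),
    mr = list(random_effects = FALSE),
    validate = list(n_validation = 5000L, centile = 0.85),
    study = list(replicates = 20L)
  )
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    config_error("unknown config key(s): %s",
                 paste(c(path, unknown[1]), collapse = "."))
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML config, overlays it on [default_config()] (rejecting
#' unknown keys) and validates the scenario block.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file (same validation).
#' @return Validated config list with a constructed `scenario_spec` and
#'   `misclass_model`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) format_error("config file not found: %s", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  cfg$scenario$seed <- cfg$seed
  cfg$spec <- do.call(scenario_spec, cfg$scenario)
  m <- cfg$misclassification
  cfg$mis <- misclass_model(
    m$mode,
    confusion = if (m$mode == "none") NULL else symmetric_confusion(m$spill),
    adult_dependence_slope = if (m$mode == "differential-on-adult")
      m$adult_dependence_slope else 0)
  cfg
}

log_stage <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(kv), unname(kv), sep = "=", collapse = " ")))
}

write_resolved_config <- function(cfg, dir) {
  keep <- setdiff(names(cfg), c("spec", "mis"))
  yaml::write_yaml(cfg[keep], file.path(dir, "resolved_config.yaml"))
}

#' Pipeline stage commands
#'
#' Each stage reads and writes documented TSV files under
#' `config$output_dir`, logs a machine-readable summary line to standard
#' error, and writes the resolved configuration beside its outputs.
#' `cmd_simulate` writes the exposure/outcome cohorts; `cmd_scan` the three
#' summary-statistic files (`early.tsv`, `adult.tsv`, `outcome.tsv`);
#' `cmd_clump` the per-exposure and joint instrument lists;
#' `cmd_harmonize` the wide harmonized tables; `cmd_mr` the univariable
#' results table; `cmd_mvmr` the multivariable fit and the decomposition
#' report (TSV plus a text block naming the life-course scenario);
#' `cmd_validate` genetic-score ROC results; `cmd_study` the
#' misclassification bias table and truth-table report.
#'
#' @param config A config list from [load_config()] (or a YAML path).
#' @return Invisibly, the main object of the stage.
#' @name pipeline_commands
NULL

as_config <- function(config) {
  if (is.character(config)) config <- load_config(config)
  if (is.null(config$spec)) config <- merge_config(load_config(), config)
  config
}

#' @rdname pipeline_commands
#' @export
cmd_simulate <- function(config) {
  cfg <- as_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  panel <- simulate_panel(cfg$spec)
  exposure <- simulate_cohort(panel, cfg$spec, cfg$samples$n_exposure, "exposure")
  outcome <- simulate_cohort(panel, cfg$spec, cfg$samples$n_outcome, "outcome")
  if (cfg$mis$mode != "none")
    exposure <- apply_misclassification(exposure, cfg$mis)
  write_cohort(exposure, cfg$output_dir, "exposure")
  write_cohort(outcome, cfg$output_dir, "outcome")
  write_resolved_config(cfg, cfg$output_dir)
  log_stage("simulate", seed = cfg$seed, variants = cfg$spec$n_variants,
            n_exposure = cfg$samples$n_exposure,
            n_outcome = cfg$samples$n_outcome,
            secs = sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(exposure = exposure, outcome = outcome))
}

#' @rdname pipeline_commands
#' @export
cmd_scan <- function(config) {
  cfg <- as_config(config)
  t0 <- Sys.time()
  exposure <- read_cohort(cfg$output_dir, "exposure", "exposure",
                          cfg$spec$outcome_model)
  outcome <- read_cohort(cfg$output_dir, "outcome", "outcome",
                         cfg$spec$outcome_model)
  early <- gwas_scan(exposure, cfg$scan$early_phenotype, cfg$scan$early_covariates)
  adult <- gwas_scan(exposure, cfg$scan$adult_phenotype, cfg$scan$adult_covariates)
  model <- if (cfg$scan$outcome_phenotype == "outcome" &&
               cfg$spec$outcome_model == "binary-logistic") "logistic" else "linear"
  out <- gwas_scan(outcome, cfg$scan$outcome_phenotype, cfg$scan$outcome_covariates,
              model = model)
  write_sumstats(early, file.path(cfg$output_dir, "early.tsv"))
  write_sumstats(adult, file.path(cfg$output_dir, "adult.tsv"))
  write_sumstats(out, file.path(cfg$output_dir, "outcome.tsv"))
  log_stage("scan", variants = nrow(early), outcome_model = model,
            secs = sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(early = early, adult = adult, outcome = out))
}

#' @rdname pipeline_commands
#' @export
cmd_clump <- function(config) {
  cfg <- as_config(config)
  t0 <- Sys.time()
  reference <- read_cohort(cfg$output_dir, "exposure")
  early <- read_sumstats(file.path(cfg$output_dir, "early.tsv"))
  adult <- read_sumstats(file.path(cfg$output_dir, "adult.tsv"))
  ce <- ld_clump(early, reference, cfg$clump$p_threshold, cfg$clump$r2_threshold)
  ca <- ld_clump(adult, reference, cfg$clump$p_threshold, cfg$clump$r2_threshold)
  joint <- cross_exposure_instrument_set(ce, ca, reference,
                                         cfg$clump$p_threshold,
                                         cfg$clump$r2_threshold)
  write_sumstats(ce, file.path(cfg$output_dir, "early_instruments.tsv"))
  write_sumstats(ca, file.path(cfg$output_dir, "adult_instruments.tsv"))
  write_sumstats(joint, file.path(cfg$output_dir, "joint_instruments.tsv"))
  log_stage("clump", early_in = nrow(early), early_out = nrow(ce),
            adult_out = nrow(ca), joint_out = nrow(joint),
            secs = sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(early = ce, adult = ca, joint = joint))
}

subset_sumstats <- function(stats, snps) {
  out <- as.data.frame(stats)[match(intersect(snps, stats$SNP), stats$SNP), ,
                              drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  out
}

#' @rdname pipeline_commands
#' @export
cmd_harmonize <- function(config) {
  cfg <- as_config(config)
  t0 <- Sys.time()
  early <- read_sumstats(file.path(cfg$output_dir, "early.tsv"))
  adult <- read_sumstats(file.path(cfg$output_dir, "adult.tsv"))
  out <- read_sumstats(file.path(cfg$output_dir, "outcome.tsv"))
  joint <- read_sumstats(file.path(cfg$output_dir, "joint_instruments.tsv"))
  einst <- read_sumstats(file.path(cfg$output_dir, "early_instruments.tsv"))
  h_joint <- harmonize(list(early = subset_sumstats(early, joint$SNP),
                            adult = subset_sumstats(adult, joint$SNP)),
                       out, cfg$harmonize$palindrome_policy,
                       cfg$harmonize$palindrome_window)
  h_early <- harmonize(list(early = subset_sumstats(early, einst$SNP)),
                       out, cfg$harmonize$palindrome_policy,
                       cfg$harmonize$palindrome_window)
  write_harmonized(h_joint, file.path(cfg$output_dir, "harmonized_joint.tsv"))
  write_harmonized(h_early, file.path(cfg$output_dir, "harmonized_early.tsv"))
  log_stage("harmonize", joint = nrow(h_joint$data), early = nrow(h_early$data),
            dropped = nrow(h_joint$drops),
            secs = sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(joint = h_joint, early = h_early))
}

#' Read a wide harmonized TSV back into a `harmonized_set`
#'
#' @param path File written by [write_harmonized()].
#' @return A `harmonized_set` (with an empty drop list).
#' @export
read_harmonized <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  dat <- utils::read.delim(path, stringsAsFactors = FALSE)
  exposures <- sub("^beta_x_", "", grep("^beta_x_", names(dat), value = TRUE))
  if (!length(exposures) || !"beta_y" %in% names(dat))
    format_error("not a harmonized table: %s", path)
  structure(list(data = dat, exposures = exposures,
                 drops = data.frame(SNP = character(), reason = character()),
                 palindrome_policy = "frequency",
                 palindrome_window = c(0.42, 0.58)),
            class = "harmonized_set")
}

#' @rdname pipeline_commands
#' @export
cmd_mr <- function(config) {
  cfg <- as_config(config)
  h_early <- read_harmonized(file.path(cfg$output_dir, "harmonized_early.tsv"))
  ivw <- mr_ivw(h_early, random_effects = cfg$mr$random_effects)
  fits <- list(ivw)
  if (nrow(h_early$data) >= 3L) fits <- c(fits, list(mr_egger(h_early)))
  tab <- do.call(mr_results_table, fits)
  utils::write.table(tab, file.path(cfg$output_dir, "mr_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("mr", beta = sprintf("%.4f", ivw$beta),
            se = sprintf("%.4f", ivw$se), n_variants = ivw$n_variants)
  invisible(fits)
}

#' @rdname pipeline_commands
#' @export
cmd_mvmr <- function(config) {
  cfg <- as_config(config)
  h_joint <- read_harmonized(file.path(cfg$output_dir, "harmonized_joint.tsv"))
  h_early <- read_harmonized(file.path(cfg$output_dir, "harmonized_early.tsv"))
  fit <- mvmr_fit(h_joint, random_effects = cfg$mr$random_effects)
  total <- mr_ivw(h_early)
  dec <- decompose_effects(total, fit, exposure = h_joint$exposures[1])
  tab <- mr_results_table(total, fit)
  utils::write.table(tab, file.path(cfg$output_dir, "mvmr_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dtab <- data.frame(exposure = dec$exposure, total = dec$total,
                     total_se = dec$total_se, direct = dec$direct,
                     direct_se = dec$direct_se, indirect = dec$indirect,
                     indirect_se_approx = dec$indirect_se,
                     scenario = dec$scenario)
  utils::write.table(dtab, file.path(cfg$output_dir, "decomposition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(utils::capture.output(print(dec)),
             file.path(cfg$output_dir, "decomposition.txt"))
  log_stage("mvmr", scenario = dec$scenario,
            direct_early = sprintf("%.4f", dec$direct),
            indirect = sprintf("%.4f", dec$indirect))
  invisible(dec)
}

#' @rdname pipeline_commands
#' @export
cmd_validate <- function(config) {
  cfg <- as_config(config)
  t0 <- Sys.time()
  einst <- read_sumstats(file.path(cfg$output_dir, "early_instruments.tsv"))
  ainst <- read_sumstats(file.path(cfg$output_dir, "adult_instruments.tsv"))
  panel <- simulate_panel(cfg$spec)
  validation <- simulate_cohort(panel, cfg$spec, cfg$validate$n_validation,
                                "outcome", seed = cfg$seed + 5L)
  early_score <- build_score(validation, score_from_sumstats(einst, "early"))
  adult_score <- build_score(validation, score_from_sumstats(ainst, "adult"))
  rows <- list()
  for (trait in c("early_latent", "adult_latent")) {
    labels <- dichotomize_at_centile(validation$phenotypes[[trait]],
                                     cfg$validate$centile)
    for (sc in c("early", "adult")) {
      auc <- roc_auc(if (sc == "early") early_score else adult_score, labels)$auc
      rows[[length(rows) + 1L]] <- data.frame(trait = trait, score = sc,
                                              auc = auc)
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(cfg$output_dir, "score_validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("validate", n = cfg$validate$n_validation,
            secs = sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(tab)
}

#' @rdname pipeline_commands
#' @param cells Optional list of study cells (see [study_grid()]); the
#'   default compares the configured scenario without misclassification
#'   against nondifferential and differential variants.
#' @export
cmd_study <- function(config, cells = NULL) {
  cfg <- as_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cells)) cells <- default_study_cells(cfg$spec)
  grid <- study_grid(cells, replicates = cfg$study$replicates,
                     n_exposure_sample = cfg$samples$n_exposure,
                     n_outcome_sample = cfg$samples$n_outcome,
                     seed = cfg$seed)
  table <- run_grid(grid)
  utils::write.table(table, file.path(cfg$output_dir, "bias_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- summarize_directions(table)
  writeLines(utils::capture.output(print(report)),
             file.path(cfg$output_dir, "misclassification_report.txt"))
  excl <- table[table$estimand == "adult_direct",
                c("cell", "reps_used", "reps_excluded")]
  utils::write.table(excl, file.path(cfg$output_dir, "excluded_replicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Default misclassification study cells
#'
#' The 2x2 of (differential?, early effect?) plus a clean no-error cell and
#' an opposite-direction early effect cell, built around a base scenario:
#' 10% symmetric self-report error; differential mode adds an
#' adult-dependence slope of 0.4 on the log-odds of over-reporting. The
#' cells use a strong-instrument architecture (per-allele effect SD 0.25)
#' so that the finite-sample nuisance biases of summary-data MVMR sit well
#' below the 3-sigma detection threshold and any flagged bias is
#' attributable to the misclassification mechanism itself.
#'
#' @param spec Base scenario (its `beta_early_direct` is overridden per
#'   cell; 0.3 encodes "early effect present").
#' @return List of cells for [study_grid()].
#' @export
default_study_cells <- function(spec = scenario_spec()) {
  spec$effect_size_sd_early <- 0.25
  spec$effect_size_sd_adult <- 0.25
  set_paths <- function(spec, early) { spec$beta_early_direct <- early; spec }
  none <- misclass_model("none")
  nondiff <- misclass_model("nondifferential", symmetric_confusion(0.1))
  diff <- misclass_model("differential-on-adult", symmetric_confusion(0.1),
                         adult_dependence_slope = 0.4)
  list(
    list(spec = set_paths(spec, 0.3), mis = none, label = "none_early"),
    list(spec = set_paths(spec, 0),   mis = nondiff, label = "nondiff_noearly"),
    list(spec = set_paths(spec, 0.3), mis = nondiff, label = "nondiff_early"),
    list(spec = set_paths(spec, 0),   mis = diff, label = "diff_noearly"),
    list(spec = set_paths(spec, 0.3), mis = diff, label = "diff_early"),
    list(spec = set_paths(spec, -0.3), mis = diff, label = "diff_early_neg")
  )
}

#' Run the full pipeline end to end
#'
#' simulate, scan, clump, harmonize, univariable MR, multivariable MR and
#' decomposition, and score validation, in order, all under
#' `config$output_dir`.
#'
#' @param config Config list or YAML path (see [load_config()]).
#' @return The [decompose_effects()] result, invisibly.
#' @export
run_pipeline <- function(config = load_config()) {
  cfg <- as_config(config)
  cmd_simulate(cfg)
  cmd_scan(cfg)
  cmd_clump(cfg)
  cmd_harmonize(cfg)
  cmd_mr(cfg)
  dec <- cmd_mvmr(cfg)
  cmd_validate(cfg)
  invisible(dec)
}
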