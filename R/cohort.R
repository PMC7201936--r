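#' Simulate an individual-level cohort under a scenario
#'
#' Generates genotypes from the panel's LD model and builds phenotypes along
#' the causal diagram: the early latent trait is genetic + confounder +
#' noise; the adult latent trait adds the mediation path from the early
#' latent and its own genetic component; both are cut into 3 categories at
#' the sample quantiles given by `spec$category_proportions` (the adult
#' measure copies the early proportions); the outcome follows a linear or
#' logistic model on the two latents and the confounder; age at menarche
#' depends on the early latent only. Covariates (age, sex, month of birth)
#' are drawn independently of everything else.
#'
#' The exposure and outcome samples of a two-sample design are obtained by
#' two calls with different seeds (the defaults derive distinct seeds from
#' `spec$seed` by sample label, so the two samples share no individuals).
#'
#' @param panel A [simulate_panel()] result.
#' @param spec The [scenario_spec()] used to build the panel.
#' @param n Number of individuals (>= 1).
#' @param sample_label `"exposure"` or `"outcome"`.
#' @param seed RNG seed for this draw; defaults to `spec$seed + 1` for the
#'   exposure sample and `spec$seed + 2` for the outcome sample.
#' @return An object of class `cohort`: list with `genotypes` (n x variants
#'   dosage matrix, columns named by variant id), `phenotypes` (data frame
#'   with id, age, sex, month_of_birth, early_latent, early_category,
#'   early_reported, adult_latent, adult_category, outcome, menarche),
#'   `variants` (the panel's variant table), `sample_label`, and
#'   `outcome_model`.
#' @examples
#' spec <- scenario_spec(n_variants = 20, seed = 3)
#' ch <- simulate_cohort(simulate_panel(spec), spec, n = 500)
#' table(ch$phenotypes$early_category)
#' @export
simulate_cohort <- function(panel, spec, n,
                            sample_label = c("exposure", "outcome"),
                            seed = NULL) {
  sample_label <- match.arg(sample_label)
  if (!inherits(panel, "variant_panel"))
    input_error("'panel' must be a variant_panel")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    input_error("'n' must be >= 1")
  n <- as.integer(n)
  if (is.null(seed))
    seed <- spec$seed + if (sample_label == "exposure") 1L else 2L
  with_seed(seed, {
    G <- draw_genotypes(panel, n)
    v <- panel$variants
    C <- stats::rnorm(n, 0, spec$confounder_sd)
    early_latent <- drop(G %*% v$beta_early) +
      spec$confounder_loading_early * C + stats::rnorm(n)
    adult_latent <- spec$beta_early_to_adult * early_latent +
      drop(G %*% v$beta_adult) +
      spec$confounder_loading_adult * C + stats::rnorm(n)
    early_category <- cut_categories(early_latent, spec$category_proportions)
    adult_category <- cut_categories(adult_latent, spec$category_proportions)
    eta <- spec$beta_early_direct * early_latent +
      spec$beta_adult_direct * adult_latent +
      spec$confounder_loading_outcome * C
    outcome <- if (spec$outcome_model == "continuous") {
      eta + stats::rnorm(n)
    } else {
      stats::rbinom(n, 1L, stats::plogis(stats::qlogis(spec$baseline_prevalence) + eta))
    }
    menarche <- spec$menarche_beta_early * early_latent + stats::rnorm(n)
    phenotypes <- data.frame(
      id = paste0(substr(sample_label, 1, 3), "_", seq_len(n)),
      age = sample(40:69, n, replace = TRUE),
      sex = stats::rbinom(n, 1L, 0.5),
      month_of_birth = sample(1:12, n, replace = TRUE),
      early_latent = early_latent,
      early_category = early_category,
      early_reported = early_category,
      adult_latent = adult_latent,
      adult_category = adult_category,
      outcome = outcome,
      menarche = menarche,
      stringsAsFactors = FALSE
    )
    structure(list(genotypes = G, phenotypes = phenotypes, variants = v,
                   sample_label = sample_label,
                   outcome_model = spec$outcome_model, seed = seed),
              class = "cohort")
  })
}

# quantile cut of a continuous trait into categories 0..2 with the given
# marginal proportions
cut_categories <- function(x, proportions) {
  q <- stats::quantile(x, cumsum(proportions)[1:2], names = FALSE)
  findInterval(x, q, left.open = TRUE)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort (%s sample): %d individuals x %d variants, %s outcome\n",
              x$sample_label, nrow(x$genotypes), ncol(x$genotypes),
              x$outcome_model))
  invisible(x)
}

#' Apply self-report misclassification to the early-life measure
#'
#' Replaces the `early_reported` column by a draw from the confusion model:
#' for each individual the reported category is sampled from the confusion
#' row of the true category; in differential mode the row is exponentially
#' tilted towards higher categories in proportion to the individual's
#' mean-centred adult latent trait (see [misclass_model()]). True categories
#' are retained in `early_category` for oracle comparisons.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param model A [misclass_model()].
#' @param seed Optional seed; defaults to the cohort's seed + 1000000.
#' @return The cohort with `phenotypes$early_reported` replaced.
#' @export
apply_misclassification <- function(cohort, model, seed = NULL) {
  if (!inherits(cohort, "cohort")) input_error("'cohort' must be a cohort")
  if (!inherits(model, "misclass_model"))
    model <- do.call(misclass_model, as.list(model))  # validates
  ph <- cohort$phenotypes
  if (model$mode == "none") {
    cohort$phenotypes$early_reported <- ph$early_category
    return(cohort)
  }
  if (is.null(seed)) seed <- cohort$seed + 1000000L
  with_seed(seed, {
    P <- model$confusion[ph$early_category + 1L, , drop = FALSE]
    if (model$mode == "differential-on-adult") {
      a <- ph$adult_latent - mean(ph$adult_latent)
      tilt <- exp(outer(model$adult_dependence_slope * a, 0:2))
      P <- P * tilt
      P <- P / rowSums(P)
    }
    u <- stats::runif(nrow(P))
    reported <- (u > P[, 1]) + (u > P[, 1] + P[, 2])
    cohort$phenotypes$early_reported <- as.integer(reported)
    cohort
  })
}

#' Write / read a cohort as plain-text tables
#'
#' The genotype matrix is written as a TSV of dosages (individuals x
#' variants, header = variant ids) and the phenotype/covariate table as a
#' second TSV (one row per individual). The variant table (alleles, blocks,
#' true effects) is written alongside so a round-tripped cohort remains
#' scannable.
#'
#' @param cohort A cohort.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_cohort` returns the three file paths invisibly;
#'   `read_cohort` returns a `cohort`.
#' @export
write_cohort <- function(cohort, dir, prefix = cohort$sample_label) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- file.path(dir, paste0(prefix, "_genotypes.tsv"))
  phen <- file.path(dir, paste0(prefix, "_phenotypes.tsv"))
  vars <- file.path(dir, paste0(prefix, "_variants.tsv"))
  utils::write.table(cohort$genotypes, geno, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$phenotypes, phen, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$variants, vars, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotypes = geno, phenotypes = phen, variants = vars))
}

#' @rdname write_cohort
#' @param sample_label Sample label to record on the read cohort.
#' @param outcome_model Outcome model label to record.
#' @export
read_cohort <- function(dir, prefix, sample_label = "exposure",
                        outcome_model = "continuous") {
  geno <- file.path(dir, paste0(prefix, "_genotypes.tsv"))
  phen <- file.path(dir, paste0(prefix, "_phenotypes.tsv"))
  vars <- file.path(dir, paste0(prefix, "_variants.tsv"))
  for (f in c(geno, phen, vars))
    if (!file.exists(f)) format_error("cohort file not found: %s", f)
  G <- as.matrix(utils::read.delim(geno, check.names = FALSE))
  storage.mode(G) <- "double"
  structure(list(genotypes = G,
                 phenotypes = utils::read.delim(phen, stringsAsFactors = FALSE),
                 variants = utils::read.delim(vars, stringsAsFactors = FALSE),
                 sample_label = sample_label,
                 outcome_model = outcome_model,
                 seed = NA_integer_),
            class = "cohort")
}
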