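#' Define a misclassification study grid
#'
#' A grid of (scenario, misclassification model) cells, each replicated,
#' used to quantify how self-report error in the early-life measure biases
#' the univariable and multivariable estimates.
#'
#' @param cells List of cells; each cell a list with elements `spec`
#'   (a [scenario_spec()]) and `mis` (a [misclass_model()]), optionally
#'   `label`.
#' @param replicates Replicates per cell (>= 1).
#' @param n_exposure_sample,n_outcome_sample Per-sample sizes.
#' @param seed Grid seed. Cell c uses base seed `seed + 10000 * (c - 1)`
#'   and replicate r within it uses `base + r`, so any cell is
#'   independently re-runnable.
#' @return Object of class `study_grid`.
#' @export
study_grid <- function(cells, replicates = 30L,
                       n_exposure_sample = 20000L, n_outcome_sample = 20000L,
                       seed = 1L) {
  if (!length(cells)) config_error("field 'cells' must be non-empty")
  replicates <- check_count(replicates, "replicates", min = 1L)
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (!inherits(cell$spec, "scenario_spec") ||
        !inherits(cell$mis, "misclass_model"))
      config_error("cell %d must have a 'spec' (scenario_spec) and a 'mis' (misclass_model)", i)
    if (is.null(cell$label)) cells[[i]]$label <- paste0("cell", i)
  }
  structure(list(cells = cells, replicates = replicates,
                 n_exposure_sample = check_count(n_exposure_sample, "n_exposure_sample", 1L),
                 n_outcome_sample = check_count(n_outcome_sample, "n_outcome_sample", 1L),
                 seed = check_count(seed, "seed")),
            class = "study_grid")
}

# category/latent slope of the early measure, from a large auxiliary cohort:
# per-variant category-scale scan betas are (to first order in the variant
# effects) this multiple of the latent-scale betas, which fixes the
# category-scale truths of the early estimands
early_category_slope <- function(spec, n_aux = 200000L) {
  spec$seed <- spec$seed + 777001L
  panel <- simulate_panel(spec)
  ch <- simulate_cohort(panel, spec, n_aux, "exposure", seed = spec$seed + 1L)
  ph <- ch$phenotypes
  stats::cov(ph$early_category, ph$early_latent) / stats::var(ph$early_latent)
}

#' Run one cell of the misclassification study
#'
#' For each replicate, simulates two independent samples, applies the
#' cell's misclassification model to the exposure sample's early measure,
#' runs the full scan-clump-harmonize-IVW+MVMR pipeline (early exposure on
#' the reported 3-category scale, adult exposure on the measured continuous
#' scale) and records the three estimands: early total, early direct and
#' adult direct. The adult-scale truth is `beta_adult_direct`; early-scale
#' truths divide the path coefficients by the category/latent slope
#' computed on a large auxiliary cohort, since the early scan is on the
#' category scale. Replicates whose clumping leaves too few instruments
#' are excluded and counted.
#'
#' @param spec Cell scenario.
#' @param mis Cell misclassification model.
#' @param reps Number of replicates.
#' @param n_exposure_sample,n_outcome_sample Per-sample sizes.
#' @param seed Cell base seed; replicate r uses `seed + r`.
#' @param label Cell label carried into the output.
#' @param selection Instrument-discovery design passed to
#'   [run_replicate()]. The default discovers instruments in an
#'   independent sample (with the cell's misclassification applied there
#'   too), so the bias table reflects the misclassification mechanism
#'   rather than winner's-curse selection bias.
#' @return A `bias_table` data frame: one row per estimand with columns
#'   `cell`, `mode`, `differential`, `beta_early_direct`,
#'   `beta_adult_direct`, `estimand`, `truth`, `mean_estimate`, `mc_se`,
#'   `bias`, `coverage`, `mean_f_early`, `reps_used`, `reps_excluded`.
#' @export
run_cell <- function(spec, mis, reps, n_exposure_sample = 20000L,
                     n_outcome_sample = 20000L, seed = 1L, label = "cell",
                     selection = "independent-sample") {
  reps <- check_count(reps, "reps", min = 1L)
  lambda <- early_category_slope(spec)
  truths <- c(
    early_total = (spec$beta_early_direct +
                     spec$beta_early_to_adult * spec$beta_adult_direct) / lambda,
    early_direct = spec$beta_early_direct / lambda,
    adult_direct = spec$beta_adult_direct
  )
  est <- matrix(NA_real_, reps, 3L,
                dimnames = list(NULL, names(truths)))
  ses <- est
  fstat <- rep(NA_real_, reps)
  excluded <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(
      run_replicate(spec, seed = seed + r,
                    n_exposure = n_exposure_sample,
                    n_outcome = n_outcome_sample, mis = mis,
                    selection = selection),
      lifecourseMR_too_few_instruments = function(e) NULL)
    if (is.null(res)) { excluded <- excluded + 1L; next }
    est[r, ] <- c(res$total_early$beta, res$mvmr$beta[["early"]],
                  res$mvmr$beta[["adult"]])
    ses[r, ] <- c(res$total_early$se, res$mvmr$se[["early"]],
                  res$mvmr$se[["adult"]])
    fstat[r] <- res$mean_f_early
  }
  used <- which(!is.na(est[, 1]))
  if (!length(used))
    input_error("all %d replicates of cell '%s' were excluded", reps, label)
  covered <- abs(sweep(est[used, , drop = FALSE], 2L, truths)) <=
    1.96 * ses[used, , drop = FALSE]
  out <- data.frame(
    cell = label,
    mode = mis$mode,
    differential = mis$mode == "differential-on-adult",
    beta_early_direct = spec$beta_early_direct,
    beta_adult_direct = spec$beta_adult_direct,
    estimand = names(truths),
    truth = unname(truths),
    mean_estimate = colMeans(est[used, , drop = FALSE]),
    mc_se = apply(est[used, , drop = FALSE], 2L, stats::sd) / sqrt(length(used)),
    bias = colMeans(est[used, , drop = FALSE]) - truths,
    coverage = colMeans(covered),
    mean_f_early = mean(fstat[used]),
    reps_used = length(used),
    reps_excluded = excluded,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Run a misclassification study grid
#'
#' Runs [run_cell()] for every cell with deterministic, independent,
#' per-cell seeds (see [study_grid()]); per-cell failures are reported and
#' do not abort the remaining cells.
#'
#' @param grid A [study_grid()].
#' @param progress Log one line per cell to standard error.
#' @return A `bias_table` with all cells' rows.
#' @export
run_grid <- function(grid, progress = TRUE) {
  if (!inherits(grid, "study_grid")) config_error("'grid' must be a study_grid")
  rows <- vector("list", length(grid$cells))
  for (i in seq_along(grid$cells)) {
    cell <- grid$cells[[i]]
    t0 <- Sys.time()
    rows[[i]] <- tryCatch(
      run_cell(cell$spec, cell$mis, grid$replicates,
               grid$n_exposure_sample, grid$n_outcome_sample,
               seed = grid$seed + 10000L * (i - 1L), label = cell$label),
      error = function(e) {
        warning(sprintf("cell '%s' failed: %s", cell$label,
                        conditionMessage(e)))
        NULL
      })
    if (progress)
      message(sprintf("[study] cell=%s reps=%d elapsed=%.1fs",
                      cell$label, grid$replicates,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Qualitative truth-table report on misclassification-induced bias
#'
#' Checks the study's three structural conclusions across the 2x2 of
#' (differential misclassification?, early effect on the outcome?): the
#' adult direct effect is flagged biased in a cell when |bias| exceeds 3
#' Monte-Carlo standard errors; bias should appear only in the
#' (differential, early-effect-present) cell; and when cells with opposite
#' early-effect directions are present, the sign of that bias should flip
#' with the direction of the early effect relative to the adult one.
#'
#' @param table A `bias_table` covering at least the 2x2 of
#'   (differential, early effect) cells.
#' @return Object of class `misclass_report`: `truth_table` (one row per
#'   cell with the adult-direct bias, its MC se and the flag),
#'   `only_expected_cell_flagged` (no flags outside the expected cells),
#'   `expected_cell_flagged` (every (differential, early-effect) cell is
#'   flagged), `sign_flips` (NA when no
#'   opposite-direction pair is present), and `attenuation` (ratio of the
#'   early instrument mean F in misclassified vs clean cells with an early
#'   effect, NA if no clean cell).
#' @export
summarize_directions <- function(table) {
  ad <- table[table$estimand == "adult_direct", , drop = FALSE]
  ad$early_effect <- ad$beta_early_direct != 0
  combos <- unique(ad[, c("differential", "early_effect")])
  need <- expand.grid(differential = c(FALSE, TRUE),
                      early_effect = c(FALSE, TRUE))
  have <- paste(combos$differential, combos$early_effect)
  missing_cells <- need[!paste(need$differential, need$early_effect) %in% have, ]
  if (nrow(missing_cells))
    input_error("grid does not cover the (differential x early-effect) cells: %s",
                paste(sprintf("(differential=%s, early_effect=%s)",
                              missing_cells$differential,
                              missing_cells$early_effect), collapse = ", "))
  ad$flagged <- abs(ad$bias) > 3 * ad$mc_se
  expected <- ad$differential & ad$early_effect
  only_expected <- !any(ad$flagged[!expected])
  expected_flagged <- all(ad$flagged[expected])
  flagged <- ad[ad$differential & ad$early_effect & ad$flagged, , drop = FALSE]
  sign_flips <- NA
  if (nrow(flagged) >= 2L && length(unique(sign(flagged$beta_early_direct))) == 2L) {
    pos <- flagged$bias[flagged$beta_early_direct > 0]
    neg <- flagged$bias[flagged$beta_early_direct < 0]
    sign_flips <- all(outer(sign(pos), sign(neg), `!=`))
  }
  clean <- table[table$mode == "none" & table$beta_early_direct != 0 &
                   table$estimand == "adult_direct", , drop = FALSE]
  mis <- ad[ad$mode != "none" & ad$early_effect, , drop = FALSE]
  attenuation <- if (nrow(clean) && nrow(mis))
    mean(mis$mean_f_early) / mean(clean$mean_f_early) else NA_real_
  structure(list(truth_table = ad[, c("cell", "mode", "differential",
                                      "early_effect", "beta_early_direct",
                                      "beta_adult_direct", "bias", "mc_se",
                                      "flagged")],
                 only_expected_cell_flagged = only_expected,
                 expected_cell_flagged = expected_flagged,
                 sign_flips = sign_flips,
                 attenuation = attenuation),
            class = "misclass_report")
}

#' @export
print.misclass_report <- function(x, ...) {
  cat("Misclassification truth table (adult direct effect)\n")
  print(x$truth_table, row.names = FALSE, digits = 3)
  cat(sprintf("no bias outside the (differential, early-effect) cell(s): %s\n",
              x$only_expected_cell_flagged))
  cat(sprintf("every (differential, early-effect) cell biased: %s\n",
              x$expected_cell_flagged))
  if (!is.na(x$sign_flips))
    cat(sprintf("bias sign flips with early-effect direction: %s\n", x$sign_flips))
  if (!is.na(x$attenuation))
    cat(sprintf("early instrument mean F, misclassified / clean: %.2f\n",
                x$attenuation))
  invisible(x)
}
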