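#' Greedy LD clumping of summary statistics
#'
#' Selects approximately independent index variants: repeatedly take the
#' smallest-p remaining variant passing `p_threshold` as an index and
#' discard every remaining variant whose squared dosage correlation with it
#' (computed in the reference genotype panel, i.e. composite LD) is at least
#' `r2_threshold`. Ties in p are broken by variant id, lexicographically,
#' for reproducibility. The defaults are genome-wide significance
#' (p < 5e-8) and near-independence (r² < 0.001).
#'
#' @param stats A `sumstats` data frame (see [gwas_scan()]).
#' @param reference A cohort whose genotypes cover all variants in `stats`.
#' @param p_threshold Index variants must have `pval < p_threshold`.
#' @param r2_threshold Variants with r² >= this against a retained index
#'   are discarded.
#' @return The retained rows of `stats`, ordered by p-value.
#' @examples
#' spec <- scenario_spec(n_variants = 20, seed = 2)
#' ch <- simulate_cohort(simulate_panel(spec), spec, 500)
#' st <- gwas_scan(ch, "early_reported")
#' ld_clump(st, ch, p_threshold = 1, r2_threshold = 0.1)
#' @export
ld_clump <- function(stats, reference, p_threshold = 5e-8,
                     r2_threshold = 0.001) {
  validate_sumstats(stats)
  G <- reference$genotypes
  missing_v <- setdiff(stats$SNP, colnames(G))
  if (length(missing_v))
    input_error("variant(s) absent from reference panel: %s",
                paste(missing_v, collapse = ", "))
  cand <- stats[stats$pval < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$pval, cand$SNP), , drop = FALSE]
  R <- suppressWarnings(stats::cor(G[, cand$SNP, drop = FALSE]))
  R[!is.finite(R)] <- 0    # constant dosage columns carry no LD information
  r2 <- R^2
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    keep[i] <- !any(keep & r2[i, seq_len(nrow(cand))] >= r2_threshold &
                      seq_len(nrow(cand)) != i)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Joint instrument set across two exposures
#'
#' Takes the union of two (individually clumped) instrument lists, keeping
#' the smaller p-value when a variant appears in both, and re-clumps the
#' union with the same greedy rule so that instruments correlated *across*
#' the two exposures are reduced to a single index variant.
#'
#' @param stats_early,stats_adult Clumped `sumstats` for the two exposures.
#' @param reference Reference cohort covering all variants.
#' @param p_threshold,r2_threshold As in [ld_clump()].
#' @return `sumstats` rows of the jointly clumped union, ordered by p.
#' @export
cross_exposure_instrument_set <- function(stats_early, stats_adult, reference,
                                          p_threshold = 5e-8,
                                          r2_threshold = 0.001) {
  validate_sumstats(stats_early)
  validate_sumstats(stats_adult)
  both <- rbind(as.data.frame(stats_early), as.data.frame(stats_adult))
  both <- both[order(both$pval, both$SNP), , drop = FALSE]
  both <- both[!duplicated(both$SNP), , drop = FALSE]
  class(both) <- c("sumstats", "data.frame")
  ld_clump(both, reference, p_threshold = p_threshold,
           r2_threshold = r2_threshold)
}
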