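canonical_sumstats_cols <- c("SNP", "effect_allele", "other_allele", "eaf",
                             "beta", "se", "pval", "samplesize")

# case-insensitive header synonyms -> canonical names
sumstats_synonyms <- c(
  snp = "SNP", rsid = "SNP", markername = "SNP", variant_id = "SNP",
  effect_allele = "effect_allele", a1 = "effect_allele", ea = "effect_allele",
  other_allele = "other_allele", a2 = "other_allele", oa = "other_allele",
  nea = "other_allele",
  eaf = "eaf", freq = "eaf", effect_allele_frequency = "eaf", af = "eaf",
  beta = "beta", b = "beta", effect = "beta",
  se = "se", stderr = "se", standard_error = "se",
  pval = "pval", p = "pval", p_value = "pval", pvalue = "pval",
  samplesize = "samplesize", n = "samplesize", sample_size = "samplesize"
)

#' @noRd
validate_sumstats <- function(stats, lines = NULL, file = NULL) {
  missing_cols <- setdiff(canonical_sumstats_cols, names(stats))
  if (length(missing_cols))
    format_error("missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", "))
  where <- function(bad) {
    if (is.null(lines)) paste0("row(s) ", paste(which(bad), collapse = ", "))
    else paste0("line(s) ", paste(lines[bad], collapse = ", "),
                if (!is.null(file)) paste0(" of ", file) else "")
  }
  fin <- is.finite(stats$se)
  bad <- (stats$se <= 0 & fin) | is.na(stats$se)
  if (any(bad)) format_error("non-positive or missing se at %s", where(bad))
  bad <- is.na(stats$pval) | stats$pval <= 0 | stats$pval > 1
  if (any(bad)) format_error("p-value outside (0, 1] at %s", where(bad))
  bad <- is.na(stats$eaf) | stats$eaf < 0 | stats$eaf > 1
  if (any(bad)) format_error("eaf outside [0, 1] at %s", where(bad))
  bad <- toupper(stats$effect_allele) == toupper(stats$other_allele)
  if (any(bad)) format_error("identical effect/other allele at %s", where(bad))
  invisible(stats)
}

#' Read / write GWAS summary statistics
#'
#' The on-disk dialect is a tab-delimited table with header
#' `SNP effect_allele other_allele eaf beta se pval samplesize`. The reader
#' accepts case-insensitive headers and common synonyms (`rsid`, `A1`,
#' `A2`, `freq`, `b`, `p`, `N`, ...); the writer emits the canonical form
#' only. Malformed rows (non-positive se, p outside (0,1], eaf outside
#' [0,1], identical alleles) are rejected with their file line numbers.
#'
#' @param path File path.
#' @return `read_sumstats` returns a `sumstats` data frame;
#'   `write_sumstats` returns `path` invisibly.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  canon <- unname(sumstats_synonyms[tolower(names(raw))])
  dup <- duplicated(canon, incomparables = NA)
  if (any(dup & !is.na(canon)))
    format_error("duplicated column(s) after header mapping: %s",
                 paste(unique(canon[dup & !is.na(canon)]), collapse = ", "))
  names(raw)[!is.na(canon)] <- canon[!is.na(canon)]
  missing_cols <- setdiff(canonical_sumstats_cols, names(raw))
  if (length(missing_cols))
    format_error("missing mandatory column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", "))
  stats <- raw[canonical_sumstats_cols]
  for (col in c("eaf", "beta", "se", "pval", "samplesize"))
    stats[[col]] <- as.numeric(stats[[col]])
  # data rows start on line 2 (after the header)
  validate_sumstats(stats, lines = seq_len(nrow(stats)) + 1L, file = path)
  class(stats) <- c("sumstats", "data.frame")
  stats
}

#' @rdname read_sumstats
#' @param stats A `sumstats` data frame.
#' @export
write_sumstats <- function(stats, path) {
  validate_sumstats(stats)
  utils::write.table(as.data.frame(stats)[canonical_sumstats_cols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
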