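#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every table to a common effect allele per variant (taken from the
#' first exposure). Where a table's effect/other alleles are swapped
#' relative to the reference, its beta is negated and its effect-allele
#' frequency complemented. Palindromic variants (A/T or G/C pairs), whose
#' strand cannot be resolved from allele labels, are handled per policy:
#' under `"frequency"` (default) they are dropped when any table's
#' effect-allele frequency lies in `palindrome_window`, and otherwise
#' aligned so that minor alleles agree across tables; `"drop"` removes all
#' palindromic variants. Any other allele-pair mismatch drops the variant
#' with a `dropped-mismatch` flag. Exposure instruments absent from the
#' outcome statistics are excluded with a warning (no LD-proxy lookup), and
#' recorded in the result's drop list.
#'
#' @param exposures A `sumstats` data frame or named list of them (one per
#'   exposure). With several exposures, only variants present in every
#'   exposure table can enter the joint design; others are dropped with
#'   reason `missing-exposure`.
#' @param outcome A `sumstats` data frame for the outcome.
#' @param palindrome_policy `"frequency"` or `"drop"`.
#' @param palindrome_window Frequency window inside which palindromic
#'   variants are considered unresolvable (default `[0.42, 0.58]`).
#' @return An object of class `harmonized_set`: list with `data` (wide data
#'   frame: `SNP`, `effect_allele`, `other_allele`, per exposure
#'   `beta_x_<label>`, `se_x_<label>`, `eaf_x_<label>`, then `beta_y`,
#'   `se_y`, `eaf_y`, and provenance `action` in
#'   `{aligned, flipped}`), `exposures` (labels), and `drops`
#'   (`SNP`, `reason`).
#' @examples
#' # see vignette("lifecourse-mr") for an end-to-end example
#' @export
harmonize <- function(exposures, outcome,
                      palindrome_policy = c("frequency", "drop"),
                      palindrome_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (inherits(exposures, "data.frame")) exposures <- list(exposures)
  if (is.null(names(exposures)) || any(names(exposures) == ""))
    names(exposures) <- paste0("exposure", seq_along(exposures))
  for (e in exposures) validate_sumstats(e)
  validate_sumstats(outcome)
  labels <- names(exposures)
  ref <- as.data.frame(exposures[[1L]])

  drops <- data.frame(SNP = character(), reason = character(),
                      stringsAsFactors = FALSE)
  drop_variant <- function(snp, reason) {
    drops <<- rbind(drops, data.frame(SNP = snp, reason = reason,
                                      stringsAsFactors = FALSE))
  }

  snps <- ref$SNP
  for (l in labels[-1L]) {
    miss <- setdiff(snps, exposures[[l]]$SNP)
    if (length(miss)) drop_variant(miss, "missing-exposure")
    snps <- intersect(snps, exposures[[l]]$SNP)
  }
  miss_out <- setdiff(snps, outcome$SNP)
  if (length(miss_out)) {
    warning(sprintf("%d instrument(s) absent from outcome statistics: %s",
                    length(miss_out), paste(miss_out, collapse = ", ")))
    drop_variant(miss_out, "missing-outcome")
    snps <- setdiff(snps, miss_out)
  }
  ref <- ref[match(snps, ref$SNP), , drop = FALSE]

  is_palindromic <- function(a1, a2) {
    p <- paste(toupper(a1), toupper(a2))
    p %in% c("A T", "T A", "G C", "C G")
  }
  ambiguous <- function(eaf) eaf >= palindrome_window[1] & eaf <= palindrome_window[2]

  # align one table to the reference alleles; returns aligned rows + status
  align <- function(tab) {
    tab <- as.data.frame(tab)[match(snps, tab$SNP), , drop = FALSE]
    status <- rep("aligned", length(snps))
    same <- toupper(tab$effect_allele) == toupper(ref$effect_allele) &
      toupper(tab$other_allele) == toupper(ref$other_allele)
    swapped <- toupper(tab$effect_allele) == toupper(ref$other_allele) &
      toupper(tab$other_allele) == toupper(ref$effect_allele)
    pal <- is_palindromic(ref$effect_allele, ref$other_allele)
    status[!same & !swapped] <- "mismatch"
    status[swapped & !pal] <- "flipped"
    if (any(pal)) {
      if (palindrome_policy == "drop") {
        status[pal] <- "palindromic"
      } else {
        # labels cannot resolve strand: drop if any frequency is ambiguous,
        # otherwise align by minor-allele agreement
        amb <- pal & (ambiguous(tab$eaf) | ambiguous(ref$eaf))
        status[amb] <- "palindromic"
        resolve <- pal & !amb & (same | swapped)
        flip <- resolve & (tab$eaf - 0.5) * (ref$eaf - 0.5) < 0
        status[resolve] <- "aligned"
        status[flip] <- "flipped"
      }
    }
    flip <- status == "flipped"
    tab$beta[flip] <- -tab$beta[flip]
    tab$eaf[flip] <- 1 - tab$eaf[flip]
    tab$effect_allele <- ref$effect_allele
    tab$other_allele <- ref$other_allele
    list(tab = tab, status = status)
  }

  aligned <- lapply(c(exposures[-1L], list(.outcome = outcome)), align)
  status <- do.call(cbind, c(list(rep("aligned", length(snps))),
                             lapply(aligned, `[[`, "status")))
  bad_mismatch <- apply(status == "mismatch", 1L, any)
  bad_pal <- apply(status == "palindromic", 1L, any) & !bad_mismatch
  if (any(bad_mismatch)) drop_variant(snps[bad_mismatch], "dropped-mismatch")
  if (any(bad_pal)) drop_variant(snps[bad_pal], "dropped-palindromic")
  keep <- !(bad_mismatch | bad_pal)

  out <- data.frame(SNP = snps, effect_allele = ref$effect_allele,
                    other_allele = ref$other_allele,
                    stringsAsFactors = FALSE)
  tabs <- c(list(list(tab = ref)), aligned[seq_along(labels[-1L])])
  for (i in seq_along(labels)) {
    tab <- tabs[[i]]$tab
    out[[paste0("beta_x_", labels[i])]] <- tab$beta
    out[[paste0("se_x_", labels[i])]] <- tab$se
    out[[paste0("eaf_x_", labels[i])]] <- tab$eaf
  }
  otab <- aligned[[".outcome"]]$tab
  out$beta_y <- otab$beta
  out$se_y <- otab$se
  out$eaf_y <- otab$eaf
  out$action <- ifelse(apply(status == "flipped", 1L, any), "flipped", "aligned")
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(data = out, exposures = labels, drops = drops,
                 palindrome_policy = palindrome_policy,
                 palindrome_window = palindrome_window),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %d variant(s), %d exposure(s) [%s]\n",
              nrow(x$data), length(x$exposures),
              paste(x$exposures, collapse = ", ")))
  if (nrow(x$drops))
    print(table(dropped = x$drops$reason))
  invisible(x)
}

# accessors used by the estimators
h_bx <- function(h, label) h$data[[paste0("beta_x_", label)]]
h_sex <- function(h, label) h$data[[paste0("se_x_", label)]]
h_by <- function(h) h$data$beta_y
h_sey <- function(h) h$data$se_y

#' Export a harmonized set as a wide TSV for audit
#'
#' @param h A `harmonized_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  utils::write.table(h$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
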