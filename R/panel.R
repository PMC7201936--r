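#' Simulate a variant panel
#'
#' Draws a panel of biallelic variants: minor-allele frequencies uniform on
#' `spec$maf_range`, allele labels (non-palindromic pairs unless
#' `spec$palindromic_alleles`), LD-block membership, and true per-allele
#' effects on the early and adult latent traits. Variants are assigned at
#' random to the early-only / adult-only / shared / null effect classes with
#' the class sizes given in the spec; effects are mean-zero Gaussian at the
#' spec's per-class scales.
#'
#' The effect allele is defined as the minor allele, so the effect-allele
#' frequency reported by [gwas_scan()] equals the simulated MAF.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `variant_panel`: a list with element
#'   `variants`, a data frame with columns `SNP`, `effect_allele`,
#'   `other_allele`, `maf`, `block`, `class`, `beta_early`, `beta_adult`,
#'   plus the LD parameters carried over from the spec.
#' @examples
#' panel <- simulate_panel(scenario_spec(n_variants = 20, seed = 7))
#' table(panel$variants$class)
#' @export
simulate_panel <- function(spec) {
  if (!inherits(spec, "scenario_spec"))
    config_error("'spec' must be a scenario_spec object")
  with_seed(spec$seed, {
    nv <- spec$n_variants
    maf <- stats::runif(nv, spec$maf_range[1], spec$maf_range[2])
    # non-palindromic ordered allele pairs; palindromic pairs optional
    pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                   c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
    if (spec$palindromic_alleles)
      pairs <- rbind(pairs, c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
    pick <- sample.int(nrow(pairs), nv, replace = TRUE)
    block <- rep(seq_len(ceiling(nv / spec$ld_block_size)),
                 each = spec$ld_block_size)[seq_len(nv)]
    cls <- rep("null", nv)
    idx <- sample.int(nv, spec$n_early_variants + spec$n_adult_variants +
                        spec$n_shared_variants)
    cls[idx] <- rep(c("early", "adult", "shared"),
                    times = c(spec$n_early_variants, spec$n_adult_variants,
                              spec$n_shared_variants))
    beta_early <- beta_adult <- numeric(nv)
    e_idx <- cls %in% c("early", "shared")
    a_idx <- cls %in% c("adult", "shared")
    beta_early[e_idx] <- stats::rnorm(sum(e_idx), 0, spec$effect_size_sd_early)
    beta_adult[a_idx] <- stats::rnorm(sum(a_idx), 0, spec$effect_size_sd_adult)
    variants <- data.frame(
      SNP = sprintf("rs%05d", seq_len(nv)),
      effect_allele = pairs[pick, 1],
      other_allele = pairs[pick, 2],
      maf = maf,
      block = block,
      class = cls,
      beta_early = beta_early,
      beta_adult = beta_adult,
      stringsAsFactors = FALSE
    )
    structure(list(variants = variants,
                   ld_block_size = spec$ld_block_size,
                   ld_rho = spec$ld_rho),
              class = "variant_panel")
  })
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("Variant panel: %d variants in %d LD block(s) (latent rho %.2f)\n",
              nrow(x$variants), length(unique(x$variants$block)), x$ld_rho))
  print(table(effect_class = x$variants$class))
  invisible(x)
}

# Genotype dosages for n individuals: two haplotypes per individual, each a
# thresholded equicorrelated Gaussian within LD block. Called inside an
# established RNG state (no set.seed here).
draw_genotypes <- function(panel, n) {
  v <- panel$variants
  nv <- nrow(v)
  rho <- panel$ld_rho
  if (rho == 0 || panel$ld_block_size == 1L) {
    # independent haplotypes: the thresholded-Gaussian model reduces to a
    # binomial dosage draw
    G <- matrix(stats::rbinom(n * nv, 2L, rep(v$maf, each = n)), n, nv)
  } else {
    thr <- stats::qnorm(v$maf)
    G <- matrix(0L, n, nv)
    for (h in 1:2) {
      Z <- matrix(stats::rnorm(n * nv), n, nv)
      U <- matrix(stats::rnorm(n * max(v$block)), n)
      Z <- sqrt(rho) * U[, v$block, drop = FALSE] + sqrt(1 - rho) * Z
      G <- G + (Z < matrix(thr, n, nv, byrow = TRUE))
    }
  }
  storage.mode(G) <- "double"
  colnames(G) <- v$SNP
  G
}
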