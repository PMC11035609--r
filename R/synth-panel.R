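#' Simulate an LD-block-structured genotype panel
#'
#' Generates biallelic dosages for `n_people_panel` individuals at
#' `n_variants` variants partitioned into `n_blocks` contiguous blocks.
#' Within a block every pair of variants has dosage correlation
#' `block_ld` by construction (LD r2 = `block_ld^2`); across blocks
#' variants are independent.
#'
#' The mechanism works at the haplotype level: each block carries a
#' shared ancestral allele indicator per haplotype, and each variant
#' copies it with probability `sqrt(block_ld)` or draws an independent
#' allele otherwise, giving exactly the target pairwise correlation for
#' any pair of distinct variants.  All variants in a block share the
#' block's minor allele frequency (drawn uniformly from `maf_range`), a
#' requirement of the exact-correlation construction.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `genotype_panel`: a list with `dosages`
#'   (people x variants integer matrix with entries in `{0, 1, 2}`,
#'   dimnames set), `variants` (data frame: `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `maf`, `block`), and
#'   `persons` (character ids).
#' @examples
#' p <- simulate_panel(sim_config(seed = 7, n_variants = 20, n_blocks = 4,
#'                                n_people_panel = 100))
#' range(p$dosages)
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "panel"), {
    n <- config$n_people_panel
    m <- config$n_variants
    b <- config$n_blocks
    sizes <- rep(m %/% b, b)
    if (m %% b > 0) sizes[seq_len(m %% b)] <- sizes[seq_len(m %% b)] + 1L
    block <- rep(seq_len(b), times = sizes)
    copy_p <- sqrt(config$block_ld)

    maf_block <- runif(b, config$maf_range[1], config$maf_range[2])
    dos <- matrix(0L, n, m)
    col0 <- 0L
    for (k in seq_len(b)) {
      mk <- sizes[k]
      p <- maf_block[k]
      for (hap in 1:2) {
        anc <- rbinom(n, 1L, p)                       # shared per block/haplotype
        cop <- matrix(rbinom(n * mk, 1L, copy_p), n, mk)
        ind <- matrix(rbinom(n * mk, 1L, p), n, mk)
        dos[, col0 + seq_len(mk)] <- dos[, col0 + seq_len(mk)] +
          cop * anc + (1L - cop) * ind
      }
      col0 <- col0 + mk
    }

    variant_id <- sprintf("rs%06d", seq_len(m))
    persons <- sprintf("P%05d", seq_len(n))
    dimnames(dos) <- list(persons, variant_id)

    # Blocks are laid down cyclically across autosomes with 5-Mb spacing,
    # so chromosome 6 naturally receives blocks in and out of the MHC.
    chrom <- as.character(((seq_len(b) - 1L) %% 22L) + 1L)
    ord_on_chrom <- stats::ave(seq_len(b), chrom, FUN = seq_along)
    base_pos <- 10e6 + (ord_on_chrom - 1) * 5e6
    pos <- as.integer(base_pos[block] +
                        (stats::ave(seq_len(m), block, FUN = seq_along) - 1L) * 1000L)

    pal <- runif(m) < config$palindromic_freq
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ea <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    oa <- character(m)
    oa[pal] <- comp[ea[pal]]
    oa[!pal] <- vapply(ea[!pal], function(a) {
      sample(setdiff(c("A", "C", "G", "T"), c(a, comp[[a]])), 1L)
    }, character(1))

    variants <- data.frame(variant_id = variant_id, chrom = chrom[block],
                           pos = pos, effect_allele = ea, other_allele = oa,
                           maf = maf_block[block], block = block,
                           stringsAsFactors = FALSE)
    structure(list(dosages = dos, variants = variants, persons = persons,
                   config = config),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d people x %d variants (%d LD blocks)\n",
              nrow(x$dosages), ncol(x$dosages), max(x$variants$block)))
  invisible(x)
}

# Dosage columns for a set of variant ids, with orientation as stored.
panel_dosages <- function(panel, variant_ids) {
  miss <- setdiff(variant_ids, colnames(panel$dosages))
  if (length(miss) > 0) {
    stop_config("variant(s) absent from panel: %s",
                paste(head(miss, 5), collapse = ", "))
  }
  panel$dosages[, variant_ids, drop = FALSE]
}
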