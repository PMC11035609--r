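#' Simulate GWAS summary statistics consistent with a genotype panel
#'
#' Draws true per-allele effects on log-WBC for `n_causal` randomly
#' chosen variants and produces single-variant association summary
#' statistics for a GWAS of effective size `gwas_n`.  Marginal (LD-
#' contaminated) effects follow from the panel's block-exchangeable
#' correlation structure; estimates are the marginal effects plus
#' sampling noise with the correct standard errors, and noise is
#' correlated within blocks as LD makes real summary statistics.
#'
#' @param panel A `genotype_panel` from [simulate_panel()].
#' @param config The [sim_config()] the panel was generated under.
#' @return A data frame of class `variant_summary` with columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta`, `p`, `eaf`, `info`.  Ground truth (true effects and the
#'   causal flag) is attached as attribute `"truth"` for testing.
#' @examples
#' cfg <- sim_config(seed = 3, n_variants = 40, n_blocks = 8,
#'                   n_people_panel = 300, n_causal = 5)
#' ss <- simulate_summary_stats(simulate_panel(cfg), cfg)
#' head(ss)
#' @export
simulate_summary_stats <- function(panel, config) {
  validate_sim_config(config)
  stopifnot(inherits(panel, "genotype_panel"))
  if (config$gwas_n < 2) stop_config("gwas_n must be at least 2")
  with_seed(derive_seed(config$seed, "gwas"), {
    v <- panel$variants
    m <- nrow(v)
    true_beta <- numeric(m)
    causal <- sort(sample.int(m, config$n_causal))
    true_beta[causal] <- rnorm(config$n_causal, 0, config$effect_sd)

    # marginal effect = own effect + LD-weighted effects of block mates
    # (dosage correlation within a block is block_ld, equal variances)
    block_sum <- tapply(true_beta, v$block, sum)[as.character(v$block)]
    marginal <- true_beta + config$block_ld * (block_sum - true_beta)

    eaf <- colMeans(panel$dosages) / 2
    sd_g <- sqrt(2 * eaf * (1 - eaf))
    var_g <- sum((true_beta * sd_g)^2)           # cross terms ignored: small
    sigma_y <- sqrt(var_g + config$wbc_log_sd_between^2)
    se <- sigma_y / (sqrt(config$gwas_n) * pmax(sd_g, 1e-8))

    # within-block exchangeable noise on the z scale mirrors the LD
    u <- rnorm(max(v$block))[v$block]
    z_noise <- sqrt(config$block_ld) * u + sqrt(1 - config$block_ld) * rnorm(m)
    beta_hat <- marginal + se * z_noise
    z <- beta_hat / se
    p <- pmax(2 * pnorm(-abs(z)), 1e-300)

    info <- 0.3 + 0.7 * stats::rbeta(m, 5, 1)

    out <- data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
                      effect_allele = v$effect_allele,
                      other_allele = v$other_allele,
                      beta = beta_hat, p = p,
                      eaf = pmin(pmax(eaf, 1e-4), 1 - 1e-4), info = info,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- data.frame(variant_id = v$variant_id,
                                     true_beta = true_beta,
                                     causal = seq_len(m) %in% causal,
                                     block = v$block)
    class(out) <- c("variant_summary", "data.frame")
    out
  })
}

#' Simulate a disease-association catalog
#'
#' Labels `n_disease_loci` variants with synthetic disease phenotype
#' names and catalog p-values below 5e-7, mimicking the catalog input
#' used to purge a polygenic score of disease-associated loci.  Half of
#' the tagged loci (where possible) are placed inside LD blocks that
#' contain a WBC-significant variant, so the catalog-LD exclusion step
#' has real work to do; the rest land in unassociated blocks.
#'
#' @param summary A `variant_summary` table from
#'   [simulate_summary_stats()] (block structure is read from its
#'   ground-truth attribute).
#' @param config The matching [sim_config()].
#' @param p_sig WBC significance threshold used to define "associated"
#'   blocks (default `5e-6`).
#' @return A data frame with columns `variant_id`, `phenotype`, `p`
#'   (all `p < 5e-7`).  Attribute `"truth"` carries each catalog
#'   variant's LD block, so tests can derive which score variants are
#'   ground-truth exclusions.
#' @export
simulate_catalog <- function(summary, config, p_sig = 5e-6) {
  validate_sim_config(config)
  truth <- attr(summary, "truth")
  if (is.null(truth)) stop_config("summary table lacks ground-truth blocks")
  if (config$n_disease_loci > nrow(summary)) {
    stop_config("n_disease_loci (%d) exceeds n_variants (%d)",
                config$n_disease_loci, nrow(summary))
  }
  if (config$n_disease_loci == 0L) {
    out <- data.frame(variant_id = character(), phenotype = character(),
                      p = numeric(), stringsAsFactors = FALSE)
    attr(out, "truth") <- data.frame(variant_id = character(),
                                     block = integer())
    return(out)
  }
  with_seed(derive_seed(config$seed, "catalog"), {
    assoc_blocks <- unique(truth$block[summary$p < p_sig])
    in_assoc <- which(truth$block %in% assoc_blocks)
    out_assoc <- setdiff(seq_len(nrow(summary)), in_assoc)
    n_in <- min(length(in_assoc), config$n_disease_loci %/% 2)
    n_out <- min(length(out_assoc), config$n_disease_loci - n_in)
    picked <- c(if (n_in > 0) sample(in_assoc, n_in),
                if (n_out > 0) sample(out_assoc, n_out))
    phen <- c(sprintf("synthetic_heme_malignancy_%02d", 1:15),
              "synthetic_lupus_like")
    out <- data.frame(variant_id = summary$variant_id[picked],
                      phenotype = sample(phen, length(picked), replace = TRUE),
                      p = 10^(-runif(length(picked), 6.5, 30)),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- data.frame(variant_id = out$variant_id,
                                     block = truth$block[picked])
    out
  })
}
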