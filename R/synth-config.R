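#' Configuration for the synthetic-data generators
#'
#' Collects every knob the generators use, with defaults chosen to mimic
#' the study conditions the pipeline was designed around: a WBC count
#' distribution with mean ~8200 and s.d. ~3900 cells/uL on the natural
#' scale, an assay lower bound of ~3900 cells/uL, and drug-exposure
#' cohorts with a leukopenia hazard ratio of 0.78 per score s.d. and a
#' ~16% first-cycle event rate.
#'
#' @param seed Integer master seed; the same seed and config reproduce
#'   every output bit-identically.
#' @param n_variants Number of variants in the panel.
#' @param n_blocks Number of contiguous LD blocks the variants are
#'   partitioned into.
#' @param block_ld Target pairwise dosage correlation within a block, in
#'   `[0, 1)`.  Squared dosage correlation (LD r2) between two variants
#'   of a block is therefore `block_ld^2`.
#' @param maf_range Pair of allele frequencies in `(0, 0.5]`; each block
#'   draws its minor allele frequency uniformly from this range.
#' @param n_people_panel Number of individuals in the genotype panel.
#' @param n_causal Number of variants with non-zero true effects on
#'   log-WBC in the simulated source GWAS.
#' @param effect_sd Standard deviation of true per-allele effects on the
#'   log-WBC scale.
#' @param n_disease_loci Number of catalog-tagged disease loci.
#' @param gwas_n Effective sample size of the simulated source GWAS.
#' @param wbc_log_mean Mean of log-WBC (log cells/uL).  The default
#'   8.91 gives a natural-scale mean of ~8200 cells/uL once combined
#'   with the default dispersion.
#' @param wbc_log_sd_between Between-person s.d. of log-WBC.
#' @param wbc_log_sd_within Within-person (repeat-measure) s.d. of
#'   log-WBC.
#' @param assay_lower,assay_upper Modal assay reference bounds in
#'   cells/uL (individual observations jitter around these, as real
#'   assays differ).
#' @param hazard_baseline Baseline leukopenia hazard, events per
#'   person-month, for the chemotherapy-like exposure cohort.
#' @param hazard_loghr_per_sd Log hazard ratio of the event per score
#'   s.d. (negative: higher benign score protects against crossing the
#'   leukopenia threshold).
#' @param score_effect Effect of the standardized score on log-WBC in
#'   the observational WBC cohort (s.d. of log-WBC per score s.d.).  The
#'   default is calibrated so the partial correlation between score and
#'   median WBC is ~0.29 at the default repeat-measure structure.
#' @param baseline_slope Effect of the score on baseline log-WBC in the
#'   exposure cohorts (default 0.062 per s.d.).
#' @param palindromic_freq Fraction of variants assigned a strand-
#'   ambiguous (A/T or C/G) allele pair.
#' @param n_biopsy Size of the bone-marrow biopsy cohort.
#' @param disc_loghr_per_sd Log hazard ratio per score s.d. for drug
#'   discontinuation in the immunosuppressant-like cohort.
#' @param disc_hazard_baseline Baseline discontinuation hazard, events
#'   per person-month.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_variants = 50, n_blocks = 10,
#'                   n_people_panel = 200)
#' panel <- simulate_panel(cfg)
#' dim(panel$dosages)
#' @export
sim_config <- function(seed = 1L,
                       n_variants = 400L,
                       n_blocks = 80L,
                       block_ld = 0.85,
                       maf_range = c(0.05, 0.5),
                       n_people_panel = 2000L,
                       n_causal = 60L,
                       effect_sd = 0.02,
                       n_disease_loci = 20L,
                       gwas_n = 2e5,
                       wbc_log_mean = 8.91,
                       wbc_log_sd_between = 0.35,
                       wbc_log_sd_within = 0.28,
                       assay_lower = 3900,
                       assay_upper = 10800,
                       hazard_baseline = 0.25,
                       hazard_loghr_per_sd = log(0.78),
                       score_effect = 0.13,
                       baseline_slope = 0.062,
                       palindromic_freq = 0.08,
                       n_biopsy = 117L,
                       disc_loghr_per_sd = log(0.62),
                       disc_hazard_baseline = 0.0015) {
  cfg <- list(seed = as.integer(seed), n_variants = as.integer(n_variants),
              n_blocks = as.integer(n_blocks), block_ld = block_ld,
              maf_range = maf_range,
              n_people_panel = as.integer(n_people_panel),
              n_causal = as.integer(n_causal), effect_sd = effect_sd,
              n_disease_loci = as.integer(n_disease_loci), gwas_n = gwas_n,
              wbc_log_mean = wbc_log_mean,
              wbc_log_sd_between = wbc_log_sd_between,
              wbc_log_sd_within = wbc_log_sd_within,
              assay_lower = assay_lower, assay_upper = assay_upper,
              hazard_baseline = hazard_baseline,
              hazard_loghr_per_sd = hazard_loghr_per_sd,
              score_effect = score_effect, baseline_slope = baseline_slope,
              palindromic_freq = palindromic_freq,
              n_biopsy = as.integer(n_biopsy),
              disc_loghr_per_sd = disc_loghr_per_sd,
              disc_hazard_baseline = disc_hazard_baseline)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_config("not a sim_config object")
  if (!is_count(cfg$n_variants)) stop_config("n_variants must be a positive integer")
  if (!is_count(cfg$n_blocks)) stop_config("n_blocks must be a positive integer")
  if (!is_count(cfg$n_people_panel)) stop_config("n_people_panel must be a positive integer")
  if (cfg$n_blocks > cfg$n_variants) {
    stop_config("n_blocks (%d) exceeds n_variants (%d)", cfg$n_blocks, cfg$n_variants)
  }
  if (cfg$block_ld < 0 || cfg$block_ld >= 1) {
    stop_config("block_ld must lie in [0, 1)")
  }
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop_config("maf_range must be an ordered pair within (0, 0.5]")
  }
  if (cfg$n_causal < 0 || cfg$n_causal > cfg$n_variants) {
    stop_config("n_causal must lie in [0, n_variants]")
  }
  if (cfg$n_disease_loci < 0) stop_config("n_disease_loci must be >= 0")
  if (cfg$palindromic_freq < 0 || cfg$palindromic_freq > 1) {
    stop_config("palindromic_freq must lie in [0, 1]")
  }
  if (cfg$assay_lower >= cfg$assay_upper) {
    stop_config("assay_lower must be below assay_upper")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration (seed", x$seed, ")\n")
  cat(sprintf("  panel: %d people x %d variants in %d LD blocks (target r = %.2f)\n",
              x$n_people_panel, x$n_variants, x$n_blocks, x$block_ld))
  cat(sprintf("  GWAS: %d causal variants, effect s.d. %.3f, n = %g\n",
              x$n_causal, x$effect_sd, x$gwas_n))
  cat(sprintf("  WBC: log-mean %.2f, between/within s.d. %.2f/%.2f, assay %g-%g\n",
              x$wbc_log_mean, x$wbc_log_sd_between, x$wbc_log_sd_within,
              x$assay_lower, x$assay_upper))
  invisible(x)
}
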