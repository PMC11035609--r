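# Shared fixtures and independent oracles used across test files.

# Small panel + summary stats generated once per test run.
tiny_setup <- function(seed = 101, n_variants = 60, n_blocks = 12,
                       n_people = 500, n_causal = 15, n_disease_loci = 6) {
  cfg <- sim_config(seed = seed, n_variants = n_variants,
                    n_blocks = n_blocks, n_people_panel = n_people,
                    n_causal = n_causal, n_disease_loci = n_disease_loci)
  panel <- simulate_panel(cfg)
  summary <- simulate_summary_stats(panel, cfg)
  list(cfg = cfg, panel = panel, summary = summary)
}

# Hand-built panel with fully controlled dosages (10 people by default).
manual_panel <- function(dosages, chrom = NULL, pos = NULL,
                         effect_allele = NULL, other_allele = NULL) {
  m <- ncol(dosages)
  ids <- colnames(dosages)
  if (is.null(ids)) ids <- sprintf("v%02d", seq_len(m))
  persons <- rownames(dosages)
  if (is.null(persons)) persons <- sprintf("p%02d", seq_len(nrow(dosages)))
  dimnames(dosages) <- list(persons, ids)
  structure(list(
    dosages = dosages,
    variants = data.frame(
      variant_id = ids,
      chrom = if (is.null(chrom)) rep("1", m) else chrom,
      pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
      effect_allele = if (is.null(effect_allele)) rep("A", m) else effect_allele,
      other_allele = if (is.null(other_allele)) rep("G", m) else other_allele,
      stringsAsFactors = FALSE),
    persons = persons, config = NULL), class = "genotype_panel")
}

# A valid summary-statistics row set over given ids.
manual_summary <- function(variant_id, p, beta = 0.1, eaf = 0.2, info = 0.9,
                           chrom = "1", pos = NULL,
                           effect_allele = "A", other_allele = "G") {
  n <- length(variant_id)
  data.frame(variant_id = variant_id, chrom = rep_len(chrom, n),
             pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
             effect_allele = rep_len(effect_allele, n),
             other_allele = rep_len(other_allele, n),
             beta = rep_len(beta, n), p = p, eaf = rep_len(eaf, n),
             info = rep_len(info, n), stringsAsFactors = FALSE)
}

# Modify fields of a sim_config while keeping its class.
cfg_mod <- function(cfg, ...) {
  m <- utils::modifyList(unclass(cfg), list(...))
  class(m) <- "sim_config"
  m
}

# Independent greedy-clumping oracle: enumerates candidates in (p, id)
# order and keeps a variant iff its r2 with every already-kept variant
# is < r2_max (equivalent to the greedy drop formulation, implemented
# differently on purpose).
oracle_clump <- function(candidates, dosages, r2_max) {
  ord <- order(candidates$p, candidates$variant_id)
  kept <- character(0)
  for (i in ord) {
    v <- candidates$variant_id[i]
    ok <- TRUE
    for (k in kept) {
      a <- dosages[, v]; b <- dosages[, k]
      r <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
      if (r^2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, v)
  }
  sort(kept)
}

# Independent quantile oracle: linear interpolation between order
# statistics at h = (n - 1) p + 1, written out by hand.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
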