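# Weighted allele-dosage scoring and per-cohort standardization.

#' Raw polygenic score per person
#'
#' `score_i = sum_j dosage_ij * weight_j` over the model's variants.
#' When a panel variant is stored with the opposite allele orientation
#' (the model's effect allele equals the panel's other allele), its
#' dosage is flipped to `2 - d`; an orientation that matches neither
#' allele is an error.  Missing dosages are mean-imputed per variant.
#'
#' @param panel A `genotype_panel`.
#' @param model A `pgs_model`.
#' @return Named numeric vector of raw scores (one per panel person),
#'   with the ids of flipped and mean-imputed variants in attributes
#'   `"flipped"` and `"imputed"`.
#' @examples
#' cfg <- sim_config(seed = 2, n_variants = 30, n_blocks = 6,
#'                   n_people_panel = 150, n_causal = 10)
#' panel <- simulate_panel(cfg)
#' ss <- simulate_summary_stats(panel, cfg)
#' model <- build_pgs(ss, panel, p_max = 0.5, region = NULL)
#' head(pgs_score(panel, model))
#' @export
pgs_score <- function(panel, model) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(model, "pgs_model"))
  v <- model$variants
  if (nrow(v) == 0L) {
    return(setNames(numeric(length(panel$persons)), panel$persons))
  }
  dos <- panel_dosages(panel, v$variant_id)
  pv <- panel$variants[match(v$variant_id, panel$variants$variant_id), ]
  same <- v$effect_allele == pv$effect_allele
  flip <- v$effect_allele == pv$other_allele
  if (any(!same & !flip)) {
    stop_config("pgs_score: effect allele matches neither panel allele for: %s",
                paste(head(v$variant_id[!same & !flip], 5), collapse = ", "))
  }
  if (any(flip)) dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  imputed <- character(0)
  if (anyNA(dos)) {
    na_col <- which(colSums(is.na(dos)) > 0)
    for (j in na_col) {
      mu <- mean(dos[, j], na.rm = TRUE)
      dos[is.na(dos[, j]), j] <- mu
    }
    imputed <- colnames(dos)[na_col]
  }
  raw <- as.vector(dos %*% v$weight)
  names(raw) <- panel$persons
  attr(raw, "flipped") <- v$variant_id[flip]
  attr(raw, "imputed") <- imputed
  raw
}

#' Standardize raw scores against a reference cohort
#'
#' Centers and scales by the mean and s.d. of the reference cohort's
#' raw scores (standardization is per analysis cohort: each cohort is
#' standardized against itself or an explicit reference).
#'
#' @param raw Raw scores to standardize.
#' @param reference Raw scores of the reference cohort (default: `raw`
#'   itself).
#' @return Numeric vector of standardized scores with attributes
#'   `"center"` and `"scale"` (the stored moments); applying the stored
#'   moments to a new raw value `x` reproduces `(x - center) / scale`.
#' @export
pgs_standardize <- function(raw, reference = raw) {
  if (length(unique(reference)) < 2L) {
    stop_config("pgs_standardize: reference cohort has fewer than 2 distinct values")
  }
  m <- mean(reference)
  s <- sd(reference)
  if (s == 0) stop_config("pgs_standardize: zero variance in reference cohort")
  z <- (raw - m) / s
  attr(z, "center") <- m
  attr(z, "scale") <- s
  z
}

#' Record standardization moments on a model
#'
#' @param model A `pgs_model`.
#' @param standardized Output of [pgs_standardize()].
#' @return The model with `standardization` set to the stored moments.
#' @export
set_standardization <- function(model, standardized) {
  stopifnot(inherits(model, "pgs_model"))
  model$standardization <- c(mean = attr(standardized, "center"),
                             sd = attr(standardized, "scale"))
  model
}
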