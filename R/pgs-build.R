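# Construction of the benign polygenic score: QC filtering, greedy LD
# clumping, region and catalog-LD exclusions, threshold selection.

#' A 1-based inclusive genomic region
#'
#' @param chrom Chromosome as a string (e.g. `"6"`).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return A `genomic_region` list.
#' @export
genomic_region <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, start <= end, start >= 1)
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end)),
            class = "genomic_region")
}

#' The major histocompatibility complex region (chromosome 6)
#'
#' The MHC is densely associated with autoimmune disease, so every
#' variant inside it is removed from the benign score regardless of
#' catalog annotation.
#'
#' @return `genomic_region("6", 25500000, 33500000)`.
#' @export
mhc_region <- function() genomic_region("6", 25500000, 33500000)

new_exclusion_log <- function() {
  data.frame(variant_id = character(), step = character(),
             detail = character(), stringsAsFactors = FALSE)
}

excluded_attr <- function(x) {
  ex <- attr(x, "excluded")
  if (is.null(ex)) new_exclusion_log() else ex
}

set_excluded <- function(x, ex) {
  attr(x, "excluded") <- ex
  x
}

PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")

#' Quality-control filter for GWAS summary statistics
#'
#' Retains variants with association `p < p_max`, minor allele frequency
#' `min(eaf, 1 - eaf) > maf_min`, imputation quality `info >= info_min`,
#' and a non-palindromic allele pair (palindromic pairs -- A/T or C/G in
#' either order -- are strand-ambiguous and dropped).
#'
#' @param summary A `variant_summary` data frame (columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `p`, `eaf`, `info`, plus
#'   `chrom`/`pos`).
#' @param p_max,maf_min,info_min Thresholds; defaults 5e-6, 0.01, 0.7.
#' @return The retained rows, with the dropped rows recorded in the
#'   `"excluded"` attribute (step `"qc"`, detail naming the failed
#'   criteria).
#' @examples
#' ss <- data.frame(variant_id = c("a", "b"), chrom = "1", pos = 1:2,
#'                  effect_allele = c("A", "A"), other_allele = c("G", "T"),
#'                  beta = 0.1, p = 1e-7, eaf = 0.2, info = 0.9)
#' qc_filter(ss)   # "b" is palindromic
#' @export
qc_filter <- function(summary, p_max = 5e-6, maf_min = 0.01, info_min = 0.7) {
  if (nrow(summary) == 0L) stop_config("qc_filter: empty summary table")
  bases <- c("A", "C", "G", "T")
  bad <- !(summary$effect_allele %in% bases & summary$other_allele %in% bases)
  if (any(bad)) {
    stop_config("qc_filter: malformed alleles in rows: %s",
                paste(head(which(bad), 10), collapse = ", "))
  }
  pair <- paste(summary$effect_allele, summary$other_allele, sep = "/")
  maf <- pmin(summary$eaf, 1 - summary$eaf)
  reasons <- cbind(p = !(summary$p < p_max),
                   maf = !(maf > maf_min),
                   info = !(summary$info >= info_min),
                   palindromic = pair %in% PALINDROMIC)
  keep <- rowSums(reasons) == 0L
  detail <- apply(reasons, 1, function(r) paste(names(r)[r], collapse = "+"))
  ex <- data.frame(variant_id = summary$variant_id[!keep],
                   step = rep("qc", sum(!keep)),
                   detail = detail[!keep], stringsAsFactors = FALSE)
  set_excluded(summary[keep, , drop = FALSE], ex)
}

#' Greedy LD clumping of candidate variants
#'
#' Sorts candidates by ascending p-value (ties broken by variant id),
#' repeatedly retains the best remaining variant and drops every
#' remaining variant whose squared dosage correlation with it is
#' `>= r2_max`.  All retained pairs therefore have `r2 < r2_max`.
#' Monomorphic dosage columns are treated as uncorrelated.
#'
#' @param candidates Summary rows surviving [qc_filter()].
#' @param panel A `genotype_panel` containing every candidate.
#' @param r2_max Squared-correlation threshold (default 0.01).
#' @return The retained rows (index variants), dropped rows logged in
#'   the `"excluded"` attribute (step `"clump"`, detail naming the index
#'   variant that absorbed them), exclusions of earlier steps preserved.
#' @export
ld_clump <- function(candidates, panel, r2_max = 0.01) {
  prior_ex <- excluded_attr(candidates)
  if (nrow(candidates) == 0L) return(set_excluded(candidates, prior_ex))
  dos <- panel_dosages(panel, candidates$variant_id)
  ord <- order(candidates$p, candidates$variant_id)
  remaining <- ord
  keep <- integer(0)
  dropped_by <- character(nrow(candidates))
  while (length(remaining) > 0) {
    best <- remaining[1]
    keep <- c(keep, best)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    r <- vapply(remaining, function(j) dosage_cor(dos[, best], dos[, j]),
                numeric(1))
    hit <- r^2 >= r2_max
    dropped_by[remaining[hit]] <- candidates$variant_id[best]
    remaining <- remaining[!hit]
  }
  keep <- sort(keep)
  drop <- setdiff(seq_len(nrow(candidates)), keep)
  ex <- rbind(prior_ex,
              data.frame(variant_id = candidates$variant_id[drop],
                         step = rep("clump", length(drop)),
                         detail = sprintf("index=%s", dropped_by[drop]),
                         stringsAsFactors = FALSE))
  set_excluded(candidates[keep, , drop = FALSE], ex)
}

#' Exclude variants inside a genomic region
#'
#' Drops variants with matching chromosome and `start <= pos <= end`
#' (1-based inclusive).  Used to purge the MHC.
#'
#' @param variants Summary rows with `chrom` and `pos`.
#' @param region A [genomic_region()]; default [mhc_region()].
#' @return Retained rows; dropped rows logged (step `"mhc"`).
#' @export
exclude_region <- function(variants, region = mhc_region()) {
  stopifnot(inherits(region, "genomic_region"))
  prior_ex <- excluded_attr(variants)
  hit <- as.character(variants$chrom) == region$chrom &
    variants$pos >= region$start & variants$pos <= region$end
  ex <- rbind(prior_ex,
              data.frame(variant_id = variants$variant_id[hit],
                         step = rep("mhc", sum(hit)),
                         detail = rep(sprintf("%s:%g-%g", region$chrom,
                                              region$start, region$end),
                                      sum(hit)),
                         stringsAsFactors = FALSE))
  set_excluded(variants[!hit, , drop = FALSE], ex)
}

#' Exclude variants in LD with disease-catalog loci
#'
#' A candidate is dropped when some catalog entry with
#' `p < catalog_p_max` has squared dosage correlation strictly greater
#' than `r2_min` with it.  Catalog variants absent from the panel are
#' skipped with a warning (their LD cannot be evaluated).
#'
#' @param variants Candidate summary rows.
#' @param catalog Data frame with `variant_id`, `phenotype`, `p`.
#' @param panel A `genotype_panel`.
#' @param catalog_p_max Catalog significance threshold (default 5e-7).
#' @param r2_min LD threshold; exclusion requires `r2 > r2_min`
#'   (default 0.5, strict inequality).
#' @return Retained rows; dropped rows logged (step `"catalog_ld"`,
#'   detail naming the triggering catalog variant and phenotype).
#' @export
exclude_catalog_ld <- function(variants, catalog, panel,
                               catalog_p_max = 5e-7, r2_min = 0.5) {
  prior_ex <- excluded_attr(variants)
  if (ncol(panel$dosages) == 0L || nrow(panel$dosages) == 0L) {
    stop_config("exclude_catalog_ld: empty genotype panel")
  }
  cat_sig <- catalog[catalog$p < catalog_p_max, , drop = FALSE]
  absent <- setdiff(unique(cat_sig$variant_id), colnames(panel$dosages))
  if (length(absent) > 0) {
    warning("catalog variant(s) absent from panel, skipped: ",
            paste(head(absent, 5), collapse = ", "))
    cat_sig <- cat_sig[!cat_sig$variant_id %in% absent, , drop = FALSE]
  }
  if (nrow(cat_sig) == 0L || nrow(variants) == 0L) {
    return(set_excluded(variants, prior_ex))
  }
  cand_dos <- panel_dosages(panel, variants$variant_id)
  cat_dos <- panel_dosages(panel, unique(cat_sig$variant_id))
  trigger <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    r2 <- vapply(seq_len(ncol(cat_dos)), function(j)
      dosage_cor(cand_dos[, i], cat_dos[, j])^2, numeric(1))
    hit <- which(r2 > r2_min)
    if (length(hit) > 0) {
      cv <- colnames(cat_dos)[hit[which.max(r2[hit])]]
      phen <- cat_sig$phenotype[match(cv, cat_sig$variant_id)]
      trigger[i] <- sprintf("catalog=%s(%s,r2=%.3f)", cv, phen, max(r2[hit]))
    }
  }
  drop <- trigger != ""
  ex <- rbind(prior_ex,
              data.frame(variant_id = variants$variant_id[drop],
                         step = rep("catalog_ld", sum(drop)),
                         detail = trigger[drop],
                         stringsAsFactors = FALSE))
  set_excluded(variants[!drop, , drop = FALSE], ex)
}

#' Build the benign polygenic score model
#'
#' Runs the full construction: [qc_filter()] at `p_max`, [ld_clump()],
#' [exclude_region()] for the MHC, and [exclude_catalog_ld()] against a
#' disease catalog.  Every input variant ends up either retained or in
#' the exclusion log, exactly once.
#'
#' @param summary Full summary-statistics table.
#' @param panel A `genotype_panel` (the LD reference).
#' @param catalog Optional disease-catalog table; `NULL` skips the
#'   catalog-LD step.
#' @param p_max,maf_min,info_min QC thresholds.
#' @param clump_r2 LD-clumping r2 threshold (default 0.01).
#' @param region Region to purge (default [mhc_region()]); `NULL`
#'   skips.
#' @param catalog_p_max,catalog_r2 Catalog-LD thresholds (defaults 5e-7
#'   and 0.5).
#' @return An object of class `pgs_model`: `variants` (data frame with
#'   `variant_id`, `effect_allele`, `weight`, `chrom`, `pos`),
#'   `exclusions` (the step-tagged log), `threshold` (`p_max`), and
#'   `standardization` (filled by [pgs_standardize()] via
#'   [set_standardization()]).
#' @export
build_pgs <- function(summary, panel, catalog = NULL, p_max = 5e-6,
                      maf_min = 0.01, info_min = 0.7, clump_r2 = 0.01,
                      region = mhc_region(), catalog_p_max = 5e-7,
                      catalog_r2 = 0.5) {
  if (anyDuplicated(summary$variant_id)) {
    stop_config("build_pgs: duplicated variant ids in summary table")
  }
  x <- qc_filter(summary, p_max = p_max, maf_min = maf_min,
                 info_min = info_min)
  x <- ld_clump(x, panel, r2_max = clump_r2)
  if (!is.null(region)) x <- exclude_region(x, region)
  if (!is.null(catalog)) {
    x <- exclude_catalog_ld(x, catalog, panel, catalog_p_max = catalog_p_max,
                            r2_min = catalog_r2)
  }
  new_pgs_model(x, excluded_attr(x), threshold = p_max)
}

new_pgs_model <- function(retained, exclusions, threshold = NA_real_,
                          standardization = c(mean = NA_real_,
                                              sd = NA_real_)) {
  variants <- data.frame(variant_id = retained$variant_id,
                         effect_allele = retained$effect_allele,
                         weight = retained$beta,
                         chrom = retained$chrom, pos = retained$pos,
                         stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  structure(list(variants = variants, exclusions = exclusions,
                 threshold = threshold, standardization = standardization),
            class = "pgs_model")
}

#' @export
print.pgs_model <- function(x, ...) {
  cat(sprintf("Polygenic score model: %d variants (p threshold %g)\n",
              nrow(x$variants), x$threshold))
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$step)
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  if (!is.na(x$standardization["mean"])) {
    cat(sprintf("  standardization: mean %.4g, sd %.4g\n",
                x$standardization["mean"], x$standardization["sd"]))
  }
  invisible(x)
}

#' Select the p-value threshold by partial correlation with measured WBC
#'
#' For each candidate threshold, builds the score end-to-end
#' ([build_pgs()] then [pgs_score()] and [pgs_standardize()]) and
#' computes the partial correlation between the standardized score and
#' the per-person median WBC count, adjusting for the requested
#' covariates.  The threshold with the highest partial correlation wins;
#' exact ties go to the most stringent threshold.
#'
#' @param summary,panel,catalog As in [build_pgs()].
#' @param wbc_cohort Data frame with one row per person: `person_id`
#'   matching the panel, `median_wbc`, and the covariate columns.
#' @param thresholds Candidate p-value thresholds (default
#'   `c(5e-8, 5e-7, 5e-6)`).
#' @param covariates Covariate column names in `wbc_cohort` (default
#'   `c("age", "sex")`; add principal-component columns to adjust for
#'   ancestry as well).
#' @param ... Further arguments passed to [build_pgs()].
#' @return A list: `threshold` (the chosen value), `correlations` (data
#'   frame of threshold, n_variants, partial_cor), `model` (the winning
#'   `pgs_model`).
#' @export
select_threshold <- function(summary, panel, wbc_cohort,
                             thresholds = c(5e-8, 5e-7, 5e-6),
                             catalog = NULL, covariates = c("age", "sex"),
                             ...) {
  stopifnot(all(c("person_id", "median_wbc") %in% names(wbc_cohort)))
  idx <- match(panel$persons, wbc_cohort$person_id)
  if (sum(!is.na(idx)) < 3L) {
    stop_config("select_threshold: fewer than 3 panel persons in wbc_cohort")
  }
  co <- wbc_cohort[idx, , drop = FALSE]
  thresholds <- sort(thresholds)            # most stringent first
  res <- lapply(thresholds, function(th) {
    model <- build_pgs(summary, panel, catalog = catalog, p_max = th, ...)
    if (nrow(model$variants) == 0L) {
      return(list(model = model, r = -Inf))
    }
    raw <- pgs_score(panel, model)
    z <- pgs_standardize(raw)
    ok <- !is.na(idx)
    r <- partial_cor(z[ok], co$median_wbc[ok],
                     co[ok, covariates, drop = FALSE])
    list(model = model, r = r)
  })
  rs <- vapply(res, `[[`, numeric(1), "r")
  best <- which.max(rs)                     # first max = most stringent
  list(threshold = thresholds[best],
       correlations = data.frame(
         threshold = thresholds,
         n_variants = vapply(res, function(x) nrow(x$model$variants),
                             integer(1)),
         partial_cor = ifelse(is.finite(rs), rs, NA_real_)),
       model = res[[best]]$model)
}

#' Sensitivity re-scoring: drop variants nominally associated with disease
#'
#' Removes from the model every variant with any listed disease
#' association `p < p_cut`, logging them under step `"sensitivity"`.
#' Downstream stages are re-run unchanged on the reduced model.
#'
#' @param model A `pgs_model`.
#' @param per_variant_assoc Data frame with `variant_id`, `phenotype`,
#'   `p` (e.g. per-variant associations with hematological
#'   malignancies).
#' @param p_cut Nominal threshold in `(0, 1)` (typical values 0.05 down
#'   to 0.001).
#' @return The reduced `pgs_model` (standardization reset: the reduced
#'   score must be re-standardized).
#' @export
sensitivity_exclude <- function(model, per_variant_assoc, p_cut = 0.05) {
  stopifnot(inherits(model, "pgs_model"), p_cut > 0, p_cut < 1)
  if (nrow(per_variant_assoc) == 0L) return(model)
  hits <- per_variant_assoc[per_variant_assoc$p < p_cut, , drop = FALSE]
  drop <- model$variants$variant_id %in% hits$variant_id
  if (!any(drop)) return(model)
  detail <- vapply(model$variants$variant_id[drop], function(v) {
    h <- hits[hits$variant_id == v, , drop = FALSE]
    sprintf("%s(p=%.3g)", h$phenotype[1], h$p[1])
  }, character(1))
  model$exclusions <- rbind(model$exclusions,
                            data.frame(variant_id =
                                         model$variants$variant_id[drop],
                                       step = "sensitivity", detail = detail,
                                       stringsAsFactors = FALSE))
  model$variants <- model$variants[!drop, , drop = FALSE]
  rownames(model$variants) <- NULL
  model$standardization <- c(mean = NA_real_, sd = NA_real_)
  model
}
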