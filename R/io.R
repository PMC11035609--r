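# Readers and writers for the pipeline's exchange formats: summary-
# statistics TSV, catalog TSV, dosage panels (matrix TSV or VCF with a
# DS field), cohort CSVs, and PGS-Catalog-style scoring files.  Every
# writer can drop a JSON sidecar echoing the generating configuration
# (seed included) next to the file.

write_sidecar <- function(path, config) {
  if (is.null(config)) return(invisible(NULL))
  jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns: `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `p`, `eaf`, `info`.
#'
#' @param summary A `variant_summary` data frame.
#' @param path Output file.
#' @param config Optional [sim_config()] echoed to a `.config.json`
#'   sidecar.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_summary_tsv <- function(summary, path, config = NULL) {
  cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "p", "eaf", "info")
  stopifnot(all(cols %in% names(summary)))
  write.table(summary[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_sidecar(path, config)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character"),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_summary", "data.frame")
  out
}

#' Write / read a disease-association catalog as TSV
#'
#' Columns: `variant_id`, `phenotype`, `p`.
#'
#' @param catalog Catalog data frame.
#' @inheritParams write_summary_tsv
#' @export
write_catalog_tsv <- function(catalog, path, config = NULL) {
  stopifnot(all(c("variant_id", "phenotype", "p") %in% names(catalog)))
  write.table(catalog[, c("variant_id", "phenotype", "p")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, config)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a dosage panel as a plain matrix TSV
#'
#' One row per variant: `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `maf`, `block`, then one dosage column per person.
#'
#' @param panel A `genotype_panel`.
#' @inheritParams write_summary_tsv
#' @export
write_panel_tsv <- function(panel, path, config = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  out <- cbind(panel$variants, as.data.frame(t(panel$dosages)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, config)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                 "other_allele", "maf", "block")
  variants <- raw[, intersect(meta_cols, names(raw)), drop = FALSE]
  persons <- setdiff(names(raw), meta_cols)
  dos <- t(as.matrix(raw[, persons, drop = FALSE]))
  dimnames(dos) <- list(persons, variants$variant_id)
  structure(list(dosages = dos, variants = variants, persons = persons,
                 config = NULL),
            class = "genotype_panel")
}

#' Write / read a dosage panel as VCF with a DS FORMAT field
#'
#' The writer emits a minimal VCFv4.2 with `GT` (dosage rounded to the
#' nearest genotype, unphased) and `DS` (the dosage itself); REF is the
#' other allele and ALT the effect allele, so DS counts effect-allele
#' copies.  The reader requires the `vcfR` package.
#'
#' @param panel A `genotype_panel`.
#' @inheritParams write_summary_tsv
#' @export
write_panel_vcf <- function(panel, path, config = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    d <- panel$dosages[, j]
    cells <- paste0(gt_code[pmin(pmax(round(d), 0), 2) + 1], ":",
                    format(d, trim = TRUE))
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS", ".", "GT:DS", cells),
          collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
                     "\"Effect-allele dosage\">"),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$persons), collapse = "\t"))
  writeLines(c(header, body), path)
  write_sidecar(path, config)
  invisible(path)
}

#' @rdname write_panel_vcf
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_config("read_panel_vcf requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         effect_allele = fix$ALT, other_allele = fix$REF,
                         stringsAsFactors = FALSE)
  dos <- t(ds)
  dimnames(dos) <- list(rownames(dos), variants$variant_id)
  structure(list(dosages = dos, variants = variants,
                 persons = rownames(dos), config = NULL),
            class = "genotype_panel")
}

#' Write the cohort bundle as CSV files
#'
#' Writes `wbc_persons.csv`, `wbc_observations.csv`, `biopsy.csv`, and
#' per exposure cohort `<type>_persons.csv` / `<type>_measures.csv`,
#' plus one `cohorts.config.json` sidecar.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @param config Optional [sim_config()] echo.
#' @return Character vector of written paths, invisibly.
#' @export
write_cohorts_csv <- function(bundle, dir, config = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$wbc$persons, "wbc_persons.csv")
  wr(bundle$wbc$observations, "wbc_observations.csv")
  wr(bundle$biopsy, "biopsy.csv")
  for (nm in c("chemo", "immuno")) {
    wr(bundle[[nm]]$persons, paste0(nm, "_persons.csv"))
    wr(bundle[[nm]]$measures, paste0(nm, "_measures.csv"))
  }
  write_sidecar(file.path(dir, "cohorts"), config)
  invisible(paths)
}

#' Write / read a scoring file (PGS-Catalog style)
#'
#' Tab-separated columns `rsID`, `effect_allele`, `effect_weight`; the
#' model's exclusion log and standardization moments go to a JSON
#' sidecar `<path>.exclusions.json`.
#'
#' @param model A `pgs_model`.
#' @param path Output file.
#' @export
write_scorefile <- function(model, path) {
  stopifnot(inherits(model, "pgs_model"))
  out <- data.frame(rsID = model$variants$variant_id,
                    effect_allele = model$variants$effect_allele,
                    effect_weight = model$variants$weight)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(threshold = model$threshold,
         standardization = as.list(model$standardization),
         exclusions = model$exclusions),
    paste0(path, ".exclusions.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname write_scorefile
#' @export
read_scorefile <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  side <- paste0(path, ".exclusions.json")
  exclusions <- new_exclusion_log()
  threshold <- NA_real_
  standardization <- c(mean = NA_real_, sd = NA_real_)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$exclusions) && length(meta$exclusions) > 0 &&
        NROW(meta$exclusions) > 0) {
      exclusions <- as.data.frame(meta$exclusions,
                                  stringsAsFactors = FALSE)
    }
    if (!is.null(meta$threshold)) threshold <- meta$threshold
    if (!is.null(meta$standardization$mean)) {
      standardization <- c(mean = as.numeric(meta$standardization$mean),
                           sd = as.numeric(meta$standardization$sd))
    }
  }
  structure(list(variants = data.frame(variant_id = tab$rsID,
                                       effect_allele = tab$effect_allele,
                                       weight = tab$effect_weight,
                                       chrom = NA_character_,
                                       pos = NA_integer_,
                                       stringsAsFactors = FALSE),
                 exclusions = exclusions, threshold = threshold,
                 standardization = standardization),
            class = "pgs_model")
}
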