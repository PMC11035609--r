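# End-to-end orchestration from one structured configuration.

#' Pipeline run configuration
#'
#' One structured object collecting the synthetic-data configuration,
#' every analysis threshold, the stage toggles and the master seed.  A
#' single master seed deterministically derives per-stage seeds, so a
#' partial re-run of any stage reproduces the full run's results.
#'
#' @param sim A [sim_config()] describing the synthetic inputs (the
#'   master seed is taken from it).
#' @param thresholds Candidate p-value thresholds for
#'   [select_threshold()].
#' @param clump_r2,catalog_r2,catalog_p_max PGS-construction thresholds.
#' @param region Genomic region to purge (default [mhc_region()]).
#' @param half_width,percentile,min_n Reference-range window settings.
#' @param strata_breaks Biopsy-count stratum boundaries (cells/uL).
#' @param chemo_rules,immuno_rules [censor_rules()] for the two
#'   exposure cohorts.
#' @param n_perm Permutations for the quintile diagnostics.
#' @param stages Character subset of
#'   `c("pgs", "quintile", "refrange", "clinassoc")`.
#' @param out_dir Optional output directory for TSV/CSV stage outputs
#'   and the JSON manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       thresholds = c(5e-8, 5e-7, 5e-6),
                       clump_r2 = 0.01, catalog_r2 = 0.5,
                       catalog_p_max = 5e-7, region = mhc_region(),
                       half_width = 0.2, percentile = 0.025, min_n = 20,
                       strata_breaks = c(0, 2500, 3000, 3500, 4000),
                       chemo_rules = censor_rules(threshold = 3000,
                                                  horizon_days = 30,
                                                  use_second_cycle = TRUE),
                       immuno_rules = censor_rules(threshold = 3000,
                                                   horizon_days = 730,
                                                   use_second_cycle = FALSE),
                       n_perm = 200L,
                       stages = c("pgs", "quintile", "refrange",
                                  "clinassoc"),
                       out_dir = NULL) {
  validate_sim_config(sim)
  stopifnot(clump_r2 > 0, clump_r2 < 1, catalog_r2 >= 0, catalog_r2 < 1,
            half_width > 0, percentile > 0, percentile < 1,
            all(stages %in% c("pgs", "quintile", "refrange", "clinassoc")))
  structure(list(sim = sim, thresholds = thresholds, clump_r2 = clump_r2,
                 catalog_r2 = catalog_r2, catalog_p_max = catalog_p_max,
                 region = region, half_width = half_width,
                 percentile = percentile, min_n = min_n,
                 strata_breaks = strata_breaks, chemo_rules = chemo_rules,
                 immuno_rules = immuno_rules, n_perm = as.integer(n_perm),
                 stages = stages, out_dir = out_dir,
                 seed = sim$seed),
            class = "run_config")
}

#' Run the full pipeline from one configuration
#'
#' Executes, in dependency order: synthetic-data generation, score
#' construction (threshold selection over the configured grid, then the
#' final purged model), quintile diagnostics, reference-range analyses,
#' and the clinical association stages.  Any stage failure aborts with
#' an error naming the stage.  Re-running with the same configuration
#' reproduces all outputs bit-exactly.
#'
#' @param config A [run_config()].
#' @return A list with the stage outputs (`panel` sizes are not
#'   returned, only results) and `manifest`: seed, package version,
#'   stage tallies, exclusion counts, and -- when `out_dir` is set --
#'   MD5 digests of every written file.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("pipeline_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL, stage = name)))
    })
  }
  out <- list()
  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("benignpgs")),
                   stages = config$stages)

  # --- synthetic inputs -------------------------------------------------
  synth <- stage("synthdata", {
    panel <- simulate_panel(config$sim)
    summary <- simulate_summary_stats(panel, config$sim)
    catalog <- simulate_catalog(summary, config$sim)
    truth <- attr(summary, "truth")
    true_raw <- as.vector(panel$dosages %*% truth$true_beta)
    true_score <- if (sd(true_raw) > 0) pgs_standardize(true_raw) else
      pgs_standardize(rnorm(length(true_raw)))
    cohorts <- simulate_cohorts(panel, as.vector(true_score), config$sim)
    list(panel = panel, summary = summary, catalog = catalog,
         cohorts = cohorts)
  })
  manifest$n_variants <- nrow(synth$summary)
  manifest$n_people <- length(synth$panel$persons)

  # --- score construction ----------------------------------------------
  ps <- stage("pgs_builder", {
    wbc_pers <- synth$cohorts$wbc$persons
    med <- person_summary(synth$cohorts$wbc$observations)
    cohort <- merge(wbc_pers, med, by = "person_id")
    sel <- select_threshold(synth$summary, synth$panel, cohort,
                            thresholds = config$thresholds,
                            catalog = synth$catalog,
                            clump_r2 = config$clump_r2,
                            region = config$region,
                            catalog_p_max = config$catalog_p_max,
                            catalog_r2 = config$catalog_r2)
    model <- sel$model
    raw <- pgs_score(synth$panel, model)
    z <- pgs_standardize(raw)
    model <- set_standardization(model, z)
    list(selection = sel, model = model, scores = z, cohort = cohort)
  })
  out$selection <- ps$selection$correlations
  out$model <- ps$model
  excl <- table(ps$model$exclusions$step)
  manifest$pgs <- list(threshold = ps$selection$threshold,
                       n_retained = nrow(ps$model$variants),
                       exclusions = as.list(excl))

  scores_by_pid <- setNames(as.vector(ps$scores), synth$panel$persons)

  # --- quintile diagnostics --------------------------------------------
  if ("quintile" %in% config$stages) {
    out$quintile <- stage("quintile_diag", {
      phen <- synthetic_null_phenome(length(synth$panel$persons),
                                     n_phen = 15,
                                     seed = derive_seed(config$seed,
                                                        "phenome"))
      covars <- ps$cohort[match(synth$panel$persons, ps$cohort$person_id),
                          c("age", "sex")]
      scan <- phenome_scan(as.vector(ps$scores), phen, covars)
      perm <- permutation_count_test(ps$model, quintile = 4,
                                     panel = synth$panel, phenotypes = phen,
                                     covariates = covars,
                                     n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, "perm"))
      quint4 <- quintile_split(ps$model)[[4]]
      binom <- per_snp_binomial(quint4, synth$panel, phen, covars)
      list(scan = scan, permutation = perm, binomial = binom)
    })
    manifest$quintile <- list(observed = out$quintile$permutation$observed,
                              empirical_p = out$quintile$permutation$p,
                              n_enriched = out$quintile$binomial$n_enriched)
  }

  # --- reference ranges -------------------------------------------------
  if ("refrange" %in% config$stages) {
    out$refrange <- stage("refrange", {
      med <- person_summary(synth$cohorts$wbc$observations)
      sc <- scores_by_pid[med$person_id]
      curves <- window_percentiles(sc, med$median_wbc,
                                   half_width = config$half_width,
                                   min_n = config$min_n)
      biopsy <- synth$cohorts$biopsy
      biopsy$score <- scores_by_pid[biopsy$person_id]
      cls <- classify_within_range(biopsy, sc, med$min_wbc,
                                   half_width = config$half_width,
                                   percentile = config$percentile,
                                   min_n = config$min_n)
      summary_tab <- stratified_summary(merge(biopsy, cls, by = "person_id"),
                                        breaks = config$strata_breaks)
      list(curves = curves, classification = cls, summary = summary_tab)
    })
    manifest$refrange <-
      list(n_grid = nrow(out$refrange$curves),
           n_classified = sum(out$refrange$classification$classifiable))
  }

  # --- clinical associations -------------------------------------------
  if ("clinassoc" %in% config$stages) {
    out$clinassoc <- stage("clinassoc", {
      med <- person_summary(synth$cohorts$wbc$observations)
      fl <- outlier_flag(synth$cohorts$wbc$observations)
      pers <- synth$cohorts$wbc$persons
      idx <- match(fl$person_id, pers$person_id)
      covars <- data.frame(age = pers$age[idx],
                           age2 = pers$age[idx]^2,
                           sex = pers$sex[idx],
                           pers[idx, paste0("PC", 1:5)])
      outlier <- logistic_fit(fl$outlier, scores_by_pid[fl$person_id],
                              covars)
      hl <- hosmer_lemeshow(outlier$diagnostics$fitted,
                            as.integer(fl$outlier), n_bins = 8)

      run_expo <- function(timeline, rules) {
        rec <- build_exposure_cohort(timeline, rules)
        rec$score_std <- as.vector(pgs_standardize(
          scores_by_pid[rec$person_id]))
        base <- linear_log_fit(log(rec$baseline_count), rec$score_std,
                               rec[, c("age", "sex", paste0("PC", 1:5))])
        cox <- cox_fit(rec, rec$score_std,
                       rec[, c("age", "sex", "dose", "duration",
                               paste0("PC", 1:5))])
        km <- km_strata(rec$score_std, rec)
        list(records = rec, baseline = base, cox = cox, km = km,
             excluded = attr(rec, "excluded"))
      }
      chemo <- run_expo(synth$cohorts$chemo, config$chemo_rules)
      immuno <- run_expo(synth$cohorts$immuno, config$immuno_rules)
      list(outlier = outlier, hosmer_lemeshow = hl, chemo = chemo,
           immuno = immuno)
    })
    manifest$clinassoc <-
      list(outlier_or = out$clinassoc$outlier$estimate,
           hl_p = out$clinassoc$hosmer_lemeshow$p,
           chemo_hr = out$clinassoc$chemo$cox$estimate,
           chemo_events = out$clinassoc$chemo$cox$events,
           immuno_hr = out$clinassoc$immuno$cox$estimate,
           chemo_excluded = length(out$clinassoc$chemo$excluded),
           immuno_excluded = length(out$clinassoc$immuno$excluded))
  }

  # --- outputs ----------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(df, name) {
      p <- file.path(config$out_dir, name)
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    paths <- c(
      write_summary_tsv(synth$summary,
                        file.path(config$out_dir, "summary_stats.tsv"),
                        config$sim),
      write_catalog_tsv(synth$catalog,
                        file.path(config$out_dir, "catalog.tsv")),
      write_scorefile(ps$model, file.path(config$out_dir, "pgs_model.tsv")),
      wp(out$selection, "threshold_selection.tsv"))
    if (!is.null(out$refrange)) {
      paths <- c(paths, wp(out$refrange$curves, "percentile_curves.tsv"),
                 wp(out$refrange$summary, "stratified_summary.tsv"))
    }
    manifest$digests <- as.list(tools::md5sum(paths))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out$manifest <- manifest
  out
}

#' Null phenome for diagnostics and calibration
#'
#' Binary phenotypes drawn independently of all genotypes and scores
#' (case prevalences uniform on `[0.05, 0.3]`), used as the null for
#' permutation-calibration checks and pipeline smoke runs.
#'
#' @param n Number of persons.
#' @param n_phen Number of phenotypes (default 15, a hematological-
#'   malignancy-sized phenome).
#' @param seed Integer seed.
#' @return Data frame of 0/1 columns `phen_01` ...
#' @export
synthetic_null_phenome <- function(n, n_phen = 15, seed = 1L) {
  with_seed(seed, {
    prev <- runif(n_phen, 0.05, 0.3)
    out <- as.data.frame(lapply(prev, function(p) rbinom(n, 1L, p)))
    names(out) <- sprintf("phen_%02d", seq_len(n_phen))
    out
  })
}
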