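# Cohort-level generators: an observational WBC cohort with repeated
# measures, a bone-marrow biopsy cohort, and two drug-exposure cohorts
# with proportional-hazards event times.

truncnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

round100 <- function(x) pmax(100, round(x / 100) * 100)

#' Simulate the full cohort bundle for the pipeline
#'
#' Given a standardized (true) score per panel person, generates:
#' * a WBC cohort with repeated log-normal WBC measurements whose
#'   person-level mean is shifted by `score_effect` per score s.d., with
#'   per-observation assay reference bounds;
#' * a biopsy cohort whose pathology outcome is drawn independently of
#'   the score (the score shifts counts, not disease);
#' * two drug-exposure timelines (chemotherapy-like, 1-month horizon
#'   with a second treatment cycle; immunosuppressant-like, 24-month
#'   horizon) with event times from the hazard
#'   `hazard_baseline * exp(loghr * score + dose effects)`.
#'
#' @param panel A `genotype_panel` (supplies person ids).
#' @param score Standardized score vector, one value per panel person.
#' @param config The matching [sim_config()].
#' @return A list of class `cohort_bundle` with elements `wbc`
#'   (`$persons`, `$observations`), `biopsy` (data frame), `chemo` and
#'   `immuno` (exposure timelines as returned by
#'   [simulate_exposure_timeline()]).
#' @export
simulate_cohorts <- function(panel, score, config) {
  validate_sim_config(config)
  stopifnot(inherits(panel, "genotype_panel"),
            length(score) == length(panel$persons))
  if (abs(mean(score)) > 0.2 || abs(sd(score) - 1) > 0.2) {
    warning("score vector does not look standardized (mean ",
            signif(mean(score), 2), ", sd ", signif(sd(score), 2), ")")
  }
  wbc <- simulate_wbc_cohort(panel$persons, score, config)
  biopsy <- simulate_biopsy_cohort(panel$persons, score, config)
  chemo <- simulate_exposure_timeline(score, config, type = "chemo",
                                      person_id = panel$persons)
  immuno <- simulate_exposure_timeline(score, config, type = "immuno",
                                       person_id = panel$persons)
  structure(list(wbc = wbc, biopsy = biopsy, chemo = chemo, immuno = immuno),
            class = "cohort_bundle")
}

# Observational WBC cohort: demographics, repeat measures, assay bounds.
simulate_wbc_cohort <- function(person_id, score, config) {
  with_seed(derive_seed(config$seed, "wbc_cohort"), {
    n <- length(person_id)
    age <- truncnorm(n, 57, 17, 18, 90)
    sex <- ifelse(runif(n) < 0.55, "F", "M")
    pcs <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(NULL, paste0("PC", 1:5)))
    persons <- data.frame(person_id = person_id, age = age, sex = sex,
                          pcs, score = score, stringsAsFactors = FALSE)
    mu_i <- config$wbc_log_mean + config$score_effect * score +
      0.02 * (sex == "F") - 0.001 * (age - 57) +
      rnorm(n, 0, config$wbc_log_sd_between)
    m_i <- sample(1:5, n, replace = TRUE)
    idx <- rep(seq_len(n), m_i)
    logw <- mu_i[idx] + rnorm(length(idx), 0, config$wbc_log_sd_within)
    # counts reported at clinical granularity (multiples of 100 cells/uL)
    count <- round100(exp(logw))
    # assay bounds vary by lab; the modal lower bound is config$assay_lower
    lower <- sample(c(config$assay_lower - 500, config$assay_lower,
                      config$assay_lower + 200),
                    length(idx), replace = TRUE, prob = c(0.2, 0.6, 0.2))
    obs <- data.frame(person_id = person_id[idx],
                      date = unlist(lapply(m_i, function(k)
                        sort(sample.int(3650, k)))),
                      count = count, assay_lower = lower,
                      assay_upper = lower + (config$assay_upper -
                                               config$assay_lower),
                      stringsAsFactors = FALSE)
    list(persons = persons, observations = obs)
  })
}

# Biopsy cohort: outcome independent of the score; counts at biopsy are
# low (that is why the biopsy happened) and lower still with pathology.
simulate_biopsy_cohort <- function(person_id, score, config) {
  with_seed(derive_seed(config$seed, "biopsy"), {
    n <- min(config$n_biopsy, length(person_id))
    pick <- sample.int(length(person_id), n)
    abnormal <- runif(n) < 0.30
    logw <- config$wbc_log_mean - 0.95 + config$score_effect * score[pick] -
      0.22 * abnormal + rnorm(n, 0, 0.22)
    data.frame(person_id = person_id[pick], score = score[pick],
               wbc_at_biopsy = round100(exp(logw)),
               other_heme_comorbidity = runif(n) < (0.45 + 0.38 * abnormal),
               outcome = ifelse(abnormal, "abnormal", "normal"),
               age = truncnorm(n, 48, 25, 18, 90),
               sex = ifelse(runif(n) < 0.55, "F", "M"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a drug-exposure timeline with proportional-hazards events
#'
#' Event (leukopenia, or count-driven discontinuation) times are drawn
#' from an exponential hazard `hazard_baseline * exp(loghr_per_sd *
#' score + 0.2 * dose_z)` and rounded up to whole days; a measured count
#' below the outcome threshold is planted on the event day, and
#' scheduled surveillance counts (all above threshold) fill the rest of
#' the observation window.  [build_exposure_cohort()] turns the timeline
#' into analysis records by applying the censoring rules.
#'
#' @param score Standardized score vector.
#' @param config A [sim_config()]; `hazard_baseline` and
#'   `hazard_loghr_per_sd` drive the chemotherapy-like cohort,
#'   `disc_hazard_baseline` and `disc_loghr_per_sd` the
#'   immunosuppressant-like cohort.
#' @param type `"chemo"` (1-month first-cycle window, second cycle ~day
#'   18-24) or `"immuno"` (24-month window, no cycles).
#' @param person_id Optional ids (defaults to `E00001...`).
#' @param threshold Outcome count threshold in cells/uL (default 3000).
#' @param seed Optional seed override; defaults to one derived from
#'   `config$seed` and `type`.
#' @return A list of class `exposure_timeline`: `persons` (one row per
#'   person: demographics, dose covariates, `baseline_count`,
#'   `second_cycle_day`, `last_encounter_day`) and `measures`
#'   (`person_id`, `day`, `count`).
#' @export
simulate_exposure_timeline <- function(score, config,
                                       type = c("chemo", "immuno"),
                                       person_id = NULL, threshold = 3000,
                                       seed = NULL) {
  validate_sim_config(config)
  type <- match.arg(type)
  if (is.null(person_id)) person_id <- sprintf("E%05d", seq_along(score))
  if (is.null(seed)) seed <- derive_seed(config$seed, paste0("expo_", type))
  with_seed(seed, {
    n <- length(score)
    if (type == "chemo") {
      age <- truncnorm(n, 60, 12, 18, 90)
      sex <- ifelse(runif(n) < 0.53, "F", "M")
      loghr <- config$hazard_loghr_per_sd
      rate_day <- config$hazard_baseline / 30.44
      second_cycle <- sample(18:24, n, replace = TRUE)
      last_enc <- rep(365L, n)
      sched <- c(7L, 14L, 21L, 28L)
    } else {
      age <- truncnorm(n, 47, 15, 18, 90)
      sex <- ifelse(runif(n) < 0.60, "F", "M")
      loghr <- config$disc_loghr_per_sd
      rate_day <- config$disc_hazard_baseline / 30.44
      second_cycle <- rep(NA_integer_, n)
      last_enc <- as.integer(round(runif(n, 90, 900)))
      sched <- seq(30L, 720L, by = 30L)
    }
    pcs <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(NULL, paste0("PC", 1:5)))
    dose_z <- rnorm(n)
    duration <- runif(n, 1, 6)
    baseline <- round100(exp(config$wbc_log_mean +
                               config$baseline_slope * score +
                               rnorm(n, 0, 0.37)))
    low_base <- runif(n) < 0.01          # a few start below the 1000 floor
    baseline[low_base] <- sample(seq(300, 900, 100), sum(low_base),
                                 replace = TRUE)

    rate <- rate_day * exp(loghr * score + 0.2 * dose_z)
    event_day <- ceiling(rexp(n, rate))

    persons <- data.frame(person_id = person_id, age = age, sex = sex, pcs,
                          dose = dose_z, duration = duration, score = score,
                          baseline_count = baseline,
                          second_cycle_day = second_cycle,
                          last_encounter_day = last_enc,
                          stringsAsFactors = FALSE)

    # surveillance counts stay above threshold; the event day (if any)
    # contributes the first and only sub-threshold measure
    sidx <- rep(seq_len(n), each = length(sched))
    meas <- data.frame(person_id = person_id[sidx],
                       day = rep(sched, n),
                       count = pmax(threshold + 200,
                                    round100(exp(config$wbc_log_mean +
                                                   config$baseline_slope *
                                                   score[sidx] +
                                                   rnorm(length(sidx), 0, 0.3)))),
                       stringsAsFactors = FALSE)
    ev <- data.frame(person_id = person_id, day = event_day,
                     count = threshold - sample(seq(100, 900, 100), n,
                                                replace = TRUE),
                     stringsAsFactors = FALSE)
    measures <- rbind(meas, ev)
    measures <- measures[order(measures$person_id, measures$day), ]
    rownames(measures) <- NULL
    structure(list(persons = persons, measures = measures, type = type,
                   threshold = threshold),
              class = "exposure_timeline")
  })
}

#' Simulate a binary outcome with a known log odds ratio per score s.d.
#'
#' Solves for the intercept that yields the requested marginal event
#' rate given the observed score distribution, then draws Bernoulli
#' outcomes from `logit(p) = a + log_or * score`.  Used for
#' parameter-recovery checks of the logistic association stage.
#'
#' @param score Standardized score vector.
#' @param log_or Generative log odds ratio per score s.d.
#' @param rate Target marginal event rate.
#' @param seed Integer seed.
#' @return Integer 0/1 vector with the solved intercept attached as
#'   attribute `"intercept"`.
#' @export
simulate_binary_outcome <- function(score, log_or, rate, seed = 1L) {
  stopifnot(rate > 0, rate < 1)
  a <- uniroot(function(a) mean(plogis(a + log_or * score)) - rate,
               interval = c(-30, 30))$root
  y <- with_seed(seed, rbinom(length(score), 1L, plogis(a + log_or * score)))
  attr(y, "intercept") <- a
  y
}
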