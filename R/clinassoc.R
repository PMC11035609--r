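# Clinical association stages: logistic models with calibration check,
# linear models on log counts, exposure-cohort construction with the
# study censoring rules, Cox models with residual diagnostics, and
# Kaplan-Meier score strata.

new_fit_result <- function(kind, estimate, ci, p, n, events = NA_integer_,
                           coef = NA_real_, se = NA_real_,
                           diagnostics = NULL) {
  structure(list(kind = kind, estimate = estimate, ci = ci, p = p, n = n,
                 events = events, coef = coef, se = se,
                 diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  lab <- switch(x$kind, logistic = "OR", cox = "HR", linear = "slope")
  cat(sprintf("%s fit: %s = %.3f [%.3f-%.3f] per s.d., p = %.3g (n = %d%s)\n",
              x$kind, lab, x$estimate, x$ci[1], x$ci[2], x$p, x$n,
              if (!is.na(x$events)) sprintf(", events = %d", x$events) else ""))
  invisible(x)
}

#' Multivariable logistic regression of a binary outcome on the score
#'
#' Maximum-likelihood logistic regression of the outcome on the
#' standardized score plus covariates; the estimate is the odds ratio
#' per score s.d. with a Wald 95% CI.  Perfect separation or
#' non-convergence raises an explicit error with diagnostics instead of
#' returning a silently unstable fit.
#'
#' @param outcome Binary 0/1 vector (both classes must be present).
#' @param score Standardized score vector.
#' @param covariates Optional covariate data frame (e.g. age,
#'   age-squared, sex, principal components).
#' @return A `fit_result` with `estimate` = OR per s.d.
#' @export
logistic_fit <- function(outcome, score, covariates = NULL) {
  stopifnot(length(outcome) == length(score))
  outcome <- as.integer(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2L) {
    stop_config("logistic_fit: outcome has a single class")
  }
  dat <- data.frame(.y = outcome, .score = score)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  sm <- summary(fit)
  b <- coef(fit)[".score"]
  se <- sm$coefficients[".score", "Std. Error"]
  if (!fit$converged || !is.finite(se) || se > 50) {
    stop_config(paste("logistic_fit: unstable fit (converged = %s, score",
                      "s.e. = %.3g); possible separation"),
                fit$converged, se)
  }
  new_fit_result("logistic", estimate = unname(exp(b)),
                 ci = unname(exp(b + c(-1, 1) * 1.96 * se)),
                 p = unname(sm$coefficients[".score", "Pr(>|z|)"]),
                 n = length(outcome), events = sum(outcome),
                 coef = unname(b), se = unname(se),
                 diagnostics = list(converged = fit$converged,
                                    fitted = fit$fitted.values))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk binning into `n_bins` equal-count groups (tied fitted
#' probabilities stay in one group), then the usual chi-square statistic
#' over observed versus expected events and non-events, with
#' `bins - 2` degrees of freedom.
#'
#' @param fitted Fitted event probabilities.
#' @param outcomes Observed 0/1 outcomes.
#' @param n_bins Number of risk bins (default 8).
#' @return A list: `statistic`, `df`, `p`, `bins` (per-bin observed and
#'   expected counts).
#' @export
hosmer_lemeshow <- function(fitted, outcomes, n_bins = 8) {
  stopifnot(length(fitted) == length(outcomes), n_bins >= 2)
  if (length(unique(fitted)) < n_bins) {
    stop_config("hosmer_lemeshow: only %d distinct probabilities for %d bins",
                length(unique(fitted)), n_bins)
  }
  br <- unique(quantile(fitted, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 7))
  g <- cut(fitted, breaks = br, include.lowest = TRUE)
  used <- nlevels(droplevels(g))
  if (used < 2L) stop_config("hosmer_lemeshow: degenerate binning")
  obs1 <- tapply(outcomes, g, sum)
  exp1 <- tapply(fitted, g, sum)
  n_g <- tapply(outcomes, g, length)
  keep <- !is.na(n_g)
  obs1 <- obs1[keep]; exp1 <- exp1[keep]; n_g <- n_g[keep]
  stat <- sum((obs1 - exp1)^2 / exp1 +
                ((n_g - obs1) - (n_g - exp1))^2 / (n_g - exp1))
  df <- length(n_g) - 2
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE),
       bins = data.frame(n = as.vector(n_g), observed = as.vector(obs1),
                         expected = as.vector(exp1)))
}

#' Linear regression of a log-transformed count on the score
#'
#' Least-squares slope per score s.d. with covariate adjustment and a
#' t-based 95% CI.  Collinear covariates raise a rank-deficiency error.
#'
#' @param log_outcome Log-transformed outcome (e.g. log baseline WBC).
#' @param score Standardized score vector.
#' @param covariates Optional covariate data frame.
#' @return A `fit_result` with `estimate` = slope per s.d.
#' @export
linear_log_fit <- function(log_outcome, score, covariates = NULL) {
  stopifnot(length(log_outcome) == length(score))
  dat <- data.frame(.y = log_outcome, .score = score)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  p_need <- ncol(dat) + 1
  if (sum(stats::complete.cases(dat)) < p_need) {
    stop_config("linear_log_fit: fewer complete cases than parameters")
  }
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(coef(fit))) {
    stop_config("linear_log_fit: rank-deficient design (collinear covariates: %s)",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  b <- coef(fit)[".score"]
  se <- sm$coefficients[".score", "Std. Error"]
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  new_fit_result("linear", estimate = unname(b),
                 ci = unname(b + c(-1, 1) * tcrit * se),
                 p = sm$coefficients[".score", "Pr(>|t|)"],
                 n = nrow(dat), coef = unname(b), se = se,
                 diagnostics = list(sigma = sm$sigma,
                                    r_squared = sm$r.squared))
}

#' Exposure-cohort censoring rules
#'
#' @param threshold Outcome count threshold in cells/uL (default 3000;
#'   3500/4000 and ANC 1500 are the supported secondary choices).
#' @param horizon_days Administrative window end: 30 days for a
#'   first-cycle chemotherapy outcome, 730 days (24 months) otherwise.
#' @param use_second_cycle Censor at the start of the second treatment
#'   cycle (chemotherapy rule).
#' @param baseline_min Baseline-count floor; persons at or below it are
#'   excluded (default 1000 cells/uL).
#' @return A list of class `censor_rules`.
#' @export
censor_rules <- function(threshold = 3000, horizon_days = 30,
                         use_second_cycle = TRUE, baseline_min = 1000) {
  stopifnot(threshold > 0, horizon_days > 0)
  structure(list(threshold = threshold, horizon_days = horizon_days,
                 use_second_cycle = use_second_cycle,
                 baseline_min = baseline_min),
            class = "censor_rules")
}

#' Build analysis records from drug-exposure timelines
#'
#' Applies the censoring rules to per-person measurement timelines: the
#' event is the first post-baseline count below `rules$threshold`;
#' otherwise the person is censored at the earliest of the second
#' treatment cycle, the administrative horizon, and the last clinical
#' encounter (ties resolved in that order).  Persons whose baseline
#' count is at or below `rules$baseline_min` are excluded and listed in
#' the `"excluded"` attribute.
#'
#' @param timeline A list with `persons` (one row per person:
#'   `person_id`, `baseline_count`, `second_cycle_day`,
#'   `last_encounter_day`, plus covariates carried through) and
#'   `measures` (`person_id`, `day`, `count`), e.g. from
#'   [simulate_exposure_timeline()].
#' @param rules A [censor_rules()] object.
#' @return Data frame with one row per included person: the carried
#'   covariates plus `time` (days), `event` (logical) and
#'   `censor_reason` (`event`, `second_cycle`, `window_end`,
#'   `last_encounter`).
#' @export
build_exposure_cohort <- function(timeline, rules = censor_rules()) {
  stopifnot(inherits(rules, "censor_rules"),
            all(c("persons", "measures") %in% names(timeline)))
  per <- timeline$persons
  mea <- timeline$measures
  if (any(mea$day < 0)) {
    stop_config("build_exposure_cohort: measurement before treatment start")
  }
  keep <- per$baseline_count > rules$baseline_min
  excluded <- per$person_id[!keep]
  per <- per[keep, , drop = FALSE]
  sub <- mea[mea$day > 0 & mea$count < rules$threshold, , drop = FALSE]
  first_event <- tapply(sub$day, sub$person_id, min)

  ev <- unname(first_event[per$person_id])
  ev[is.na(ev)] <- Inf
  sc <- if (rules$use_second_cycle) as.numeric(per$second_cycle_day)
        else rep(NA_real_, nrow(per))
  sc[is.na(sc)] <- Inf
  le <- as.numeric(per$last_encounter_day)
  le[is.na(le)] <- Inf
  we <- rep(rules$horizon_days, nrow(per))
  cand <- cbind(event = ev, second_cycle = sc, window_end = we,
                last_encounter = le)
  j <- max.col(-cand, ties.method = "first")   # ties: priority order
  out <- per
  out$time <- cand[cbind(seq_len(nrow(per)), j)]
  out$censor_reason <- colnames(cand)[j]
  out$event <- out$censor_reason == "event"
  rownames(out) <- NULL
  if (any(out$time <= 0)) {
    stop_config("build_exposure_cohort: event/censor time not positive for %s",
                paste(head(out$person_id[out$time <= 0], 5), collapse = ", "))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Cox proportional-hazards fit with residual diagnostics
#'
#' Partial-likelihood estimation (Efron tie handling by default) of the
#' hazard ratio per score s.d., with Wald 95% CI and a diagnostics
#' report: Schoenfeld-residual tests of proportional hazards
#' ([survival::cox.zph()]), and martingale and deviance residual
#' summaries for non-linearity and outliers.
#'
#' @param records Exposure records from [build_exposure_cohort()]
#'   (columns `time`, `event`).
#' @param score Standardized score, aligned with `records` rows (or a
#'   column name in `records`).
#' @param covariates Optional covariate data frame (or column names in
#'   `records`).
#' @param ties Tie-handling method (default `"efron"`).
#' @return A `fit_result` with `estimate` = HR per s.d.; `diagnostics`
#'   holds `zph` (the proportional-hazards table), `martingale` and
#'   `deviance` residual summaries, and the fitted model.
#' @export
cox_fit <- function(records, score, covariates = NULL, ties = "efron") {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (sum(records$event) < 1L) {
    stop_config("cox_fit: no events in the cohort")
  }
  if (is.character(score) && length(score) == 1L) score <- records[[score]]
  if (is.character(covariates)) {
    covariates <- records[, covariates, drop = FALSE]
  }
  dat <- data.frame(.time = records$time, .event = as.integer(records$event),
                    .score = score)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  rhs <- setdiff(names(dat), c(".time", ".event"))
  form <- stats::reformulate(sprintf("`%s`", rhs),
                             response = quote(survival::Surv(.time, .event)))
  fit <- survival::coxph(form, data = dat, ties = ties)
  sm <- summary(fit)
  b <- coef(fit)[".score"]
  se <- sqrt(diag(vcov(fit)))[".score"]
  zph <- tryCatch(survival::cox.zph(fit)$table, error = function(e) NULL)
  mart <- residuals(fit, type = "martingale")
  devr <- residuals(fit, type = "deviance")
  new_fit_result("cox", estimate = unname(exp(b)),
                 ci = unname(exp(b + c(-1, 1) * 1.96 * se)),
                 p = sm$coefficients[".score", "Pr(>|z|)"],
                 n = nrow(dat), events = sum(dat$.event),
                 coef = unname(b), se = unname(se),
                 diagnostics = list(zph = zph,
                                    martingale = summary(mart),
                                    deviance = summary(devr),
                                    n_large_deviance = sum(abs(devr) > 2.5),
                                    model = fit))
}

#' Kaplan-Meier strata by standardized score
#'
#' Strata: Low (`score < -1`), Middle (`-1 <= score <= 1`), High
#' (`score > 1`); a score of exactly -1 or 1 is Middle.  Returns the
#' per-person labels and the product-limit survival estimate per
#' stratum.
#'
#' @param scores Standardized score vector.
#' @param records Exposure records with `time` and `event`.
#' @return A list: `labels` (factor Low/Middle/High) and `fit` (a
#'   [survival::survfit] object over the non-empty strata).
#' @export
km_strata <- function(scores, records) {
  stopifnot(length(scores) == nrow(records))
  labels <- factor(ifelse(scores < -1, "Low",
                          ifelse(scores > 1, "High", "Middle")),
                   levels = c("Low", "Middle", "High"))
  dat <- data.frame(time = records$time, event = as.integer(records$event),
                    stratum = labels)
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = dat)
  list(labels = labels, fit = fit)
}
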