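# Logistic, calibration, linear, exposure-cohort construction, Cox and
# Kaplan-Meier stages.

test_that("logistic_fit is null-consistent and matches the 2x2 closed form", {
  n <- 10000
  score <- with_seed(81, as.vector(scale(rnorm(n))))
  y <- simulate_binary_outcome(score, log_or = 0, rate = 0.15, seed = 82)
  f <- logistic_fit(y, score)
  expect_lt(abs(f$estimate - 1), 0.1)
  expect_true(f$ci[1] < 1 && 1 < f$ci[2])
  expect_equal(f$events, sum(y))

  # dichotomized score, no covariates: OR = ad / bc
  xb <- as.integer(score > 0)
  tab <- table(xb, y)
  or_closed <- (tab["1", "1"] * tab["0", "0"]) /
    (tab["0", "1"] * tab["1", "0"])
  f2 <- logistic_fit(y, xb)
  expect_equal(f2$estimate, unname(or_closed), tolerance = 1e-6)

  expect_error(logistic_fit(rep(0L, 10), rnorm(10)), "single class")
  # perfect separation is surfaced, not silently returned
  ys <- as.integer(score > 1)
  expect_error(logistic_fit(ys, score), "separation")
})

test_that("hosmer_lemeshow uses 8 bins by default and detects
          mis-calibration", {
  n <- 10000
  score <- with_seed(83, as.vector(scale(rnorm(n))))
  y <- simulate_binary_outcome(score, log_or = 0.8, rate = 0.2, seed = 84)
  f <- logistic_fit(y, score)
  hl <- hosmer_lemeshow(f$diagnostics$fitted, y)
  expect_equal(nrow(hl$bins), 8L)
  expect_equal(hl$df, 6)
  expect_gt(hl$p, 0.01)              # correctly specified model fits
  # squared probabilities are badly calibrated
  hl_bad <- hosmer_lemeshow(f$diagnostics$fitted^2, y)
  expect_lt(hl_bad$p, 1e-6)
  expect_error(hosmer_lemeshow(rep(c(0.1, 0.2), 50), rep(0:1, 50), 8),
               "distinct")
})

test_that("hosmer_lemeshow p is roughly uniform under correct
          specification", {
  n <- 2000
  ps <- vapply(1:60, function(r) {
    score <- with_seed(1000 + r, as.vector(scale(rnorm(n))))
    y <- simulate_binary_outcome(score, log_or = 0.5, rate = 0.2,
                                 seed = 2000 + r)
    f <- logistic_fit(y, score)
    hosmer_lemeshow(f$diagnostics$fitted, y)$p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.2)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("linear_log_fit recovers exact and null slopes and rejects
          collinear designs", {
  x <- with_seed(85, rnorm(200))
  f <- suppressWarnings(linear_log_fit(x, x))  # exact fit: lm warns
  expect_equal(f$estimate, 1, tolerance = 1e-10)
  expect_lt(f$diagnostics$sigma, 1e-10)
  # permuted score: slope ~ 0
  y <- 5 + 0.3 * x + with_seed(86, rnorm(200, 0, 0.5))
  f0 <- linear_log_fit(y, with_seed(87, sample(x)))
  expect_true(f0$ci[1] < 0 && 0 < f0$ci[2])
  expect_error(linear_log_fit(y, x, data.frame(x2 = x)), "collinear")
  expect_error(linear_log_fit(y[1:2], x[1:2], data.frame(z = 1:2)),
               "complete cases")
})

test_that("build_exposure_cohort applies event-before-censor logic and the
          baseline floor", {
  persons <- data.frame(person_id = c("ev", "cyc", "low"),
                        baseline_count = c(8000, 8000, 900),
                        second_cycle_day = c(21L, 21L, 21L),
                        last_encounter_day = 365L,
                        stringsAsFactors = FALSE)
  measures <- data.frame(person_id = c("ev", "cyc"),
                         day = c(10L, 14L), count = c(2500, 5000))
  rec <- build_exposure_cohort(list(persons = persons, measures = measures),
                               censor_rules())
  expect_equal(rec$time[rec$person_id == "ev"], 10)
  expect_true(rec$event[rec$person_id == "ev"])
  expect_identical(rec$censor_reason[rec$person_id == "ev"], "event")
  # no sub-threshold count: censored at the second cycle (day 21 < 30)
  expect_equal(rec$time[rec$person_id == "cyc"], 21)
  expect_identical(rec$censor_reason[rec$person_id == "cyc"],
                   "second_cycle")
  # baseline 900 <= 1000: excluded with a log entry
  expect_false("low" %in% rec$person_id)
  expect_identical(attr(rec, "excluded"), "low")
  # conservation: input persons = included + excluded
  expect_equal(nrow(rec) + length(attr(rec, "excluded")), nrow(persons))
  # horizon censoring without a second cycle
  persons2 <- data.frame(person_id = "h", baseline_count = 8000,
                         second_cycle_day = NA_integer_,
                         last_encounter_day = 900L)
  rec2 <- build_exposure_cohort(list(persons = persons2,
                                     measures = measures[0, ]),
                                censor_rules(horizon_days = 730,
                                             use_second_cycle = FALSE))
  expect_equal(rec2$time, 730)
  expect_identical(rec2$censor_reason, "window_end")
  # a last encounter before the horizon wins
  persons2$last_encounter_day <- 200L
  rec3 <- build_exposure_cohort(list(persons = persons2,
                                     measures = measures[0, ]),
                                censor_rules(horizon_days = 730,
                                             use_second_cycle = FALSE))
  expect_identical(rec3$censor_reason, "last_encounter")
  # measurements before start are invalid
  bad <- list(persons = persons2,
              measures = data.frame(person_id = "h", day = -1, count = 100))
  expect_error(build_exposure_cohort(bad, censor_rules()), "before")
})

test_that("cox_fit is null-consistent, rank-invariant and diagnosable", {
  cfg <- sim_config(seed = 91, n_causal = 0, hazard_loghr_per_sd = 0)
  score <- with_seed(92, as.vector(scale(rnorm(2000))))
  tl <- simulate_exposure_timeline(score, cfg, type = "chemo")
  rec <- build_exposure_cohort(tl, censor_rules())
  f <- cox_fit(rec, "score", c("age", "dose"))
  expect_true(f$ci[1] < 1 && 1 < f$ci[2])
  expect_true(f$events >= 1 && f$events <= f$n)
  expect_false(is.null(f$diagnostics$zph))
  expect_true(all(f$diagnostics$martingale <= 1))
  # doubling all times leaves the HR unchanged (partial likelihood ranks)
  rec2 <- rec; rec2$time <- rec2$time * 2
  f2 <- cox_fit(rec2, "score", c("age", "dose"))
  expect_equal(f2$estimate, f$estimate, tolerance = 1e-10)
  # no events is an explicit error
  rec0 <- rec; rec0$event <- FALSE
  expect_error(cox_fit(rec0, "score"), "no events")
})

test_that("km_strata cuts at +/-1 s.d. with closed middle and produces
          proper survival curves", {
  rec <- data.frame(time = c(5, 10, 15, 20, 25, 30),
                    event = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  sc <- c(-1.5, -1.0, 0, 1.0, 1.5, 0.2)
  km <- km_strata(sc, rec)
  expect_identical(as.character(km$labels),
                   c("Low", "Middle", "Middle", "Middle", "High", "Middle"))
  # curves are non-increasing step functions starting at 1
  s <- summary(km$fit)
  expect_true(all(s$surv <= 1))
  for (st in unique(s$strata)) {
    expect_false(is.unsorted(rev(s$surv[s$strata == st])))
  }
  # all scores zero: a single Middle stratum
  km0 <- km_strata(rep(0, 6), rec)
  expect_equal(nlevels(droplevels(km0$labels)), 1L)
})
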