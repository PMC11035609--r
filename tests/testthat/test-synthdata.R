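# Properties of the synthetic-data generators: determinism, dosage and
# frequency bounds, LD structure, GWAS sampling behaviour, catalog
# construction, and cohort generative targets.

test_that("generators are deterministic under a fixed seed and config", {
  cfg <- sim_config(seed = 7, n_variants = 30, n_blocks = 6,
                    n_people_panel = 80, n_causal = 5, n_disease_loci = 4)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$variants, p2$variants)
  s1 <- simulate_summary_stats(p1, cfg)
  s2 <- simulate_summary_stats(p2, cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_catalog(s1, cfg), simulate_catalog(s2, cfg))
  sc <- as.vector(scale(as.vector(p1$dosages %*% rnorm(30, 0, 0.02))))
  expect_identical(simulate_cohorts(p1, sc, cfg),
                   simulate_cohorts(p1, sc, cfg))
  # a different seed changes the data
  cfg2 <- sim_config(seed = 8, n_variants = 30, n_blocks = 6,
                     n_people_panel = 80, n_causal = 5)
  expect_false(identical(simulate_panel(cfg2)$dosages, p1$dosages))
})

test_that("panel dosages respect bounds, frequencies and block LD", {
  cfg <- sim_config(seed = 3, n_variants = 40, n_blocks = 8, block_ld = 0.9,
                    n_people_panel = 5000, maf_range = c(0.1, 0.4),
                    n_causal = 0)
  p <- simulate_panel(cfg)
  expect_true(all(p$dosages %in% 0:2))
  expect_identical(colnames(p$dosages), p$variants$variant_id)
  freq <- colMeans(p$dosages) / 2
  expect_true(all(abs(freq - p$variants$maf) < 0.03))
  expect_true(all(p$variants$maf >= 0.1 & p$variants$maf <= 0.4))

  # within-block r2 targets block_ld^2 = 0.81 (checked by brute-force
  # column correlation); across blocks ~ 0
  r2_within <- unlist(lapply(split(seq_len(40), p$variants$block),
                             function(ix) {
    r2 <- dosage_r2_matrix(p$dosages[, ix])
    r2[upper.tri(r2)]
  }))
  expect_lt(abs(mean(r2_within) - 0.81), 0.05)

  cfg0 <- sim_config(seed = 4, block_ld = 0, n_variants = 40, n_blocks = 8,
                     n_people_panel = 5000, n_causal = 0)
  p0 <- simulate_panel(cfg0)
  r2_0 <- unlist(lapply(split(seq_len(40), p0$variants$block),
                        function(ix) {
    r2 <- dosage_r2_matrix(p0$dosages[, ix])
    r2[upper.tri(r2)]
  }))
  expect_lt(mean(r2_0), 0.01)
})

test_that("panel configuration errors are caught", {
  expect_error(sim_config(n_variants = 0), "n_variants")
  expect_error(sim_config(block_ld = 1), "block_ld")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_blocks = 10, n_variants = 5), "exceeds")
})

test_that("null GWAS gives a 5% nominal rate; strong effects give tiny p", {
  cfg <- sim_config(seed = 5, n_variants = 2000, n_blocks = 2000,
                    block_ld = 0, n_people_panel = 300, n_causal = 0)
  ss <- simulate_summary_stats(simulate_panel(cfg), cfg)
  # binomial error band: 0.05 +/- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  expect_true(all(ss$p > 0 & ss$p <= 1))
  expect_true(all(ss$info >= 0.3 & ss$info <= 1))

  cfgb <- sim_config(seed = 6, n_variants = 50, n_blocks = 50,
                     n_people_panel = 400, n_causal = 25, effect_sd = 0.08,
                     gwas_n = 1e5)
  ssb <- simulate_summary_stats(simulate_panel(cfgb), cfgb)
  tr <- attr(ssb, "truth")
  big <- tr$causal & abs(tr$true_beta) > 0.05
  expect_true(all(ssb$p[big] < 5e-6))
  expect_error(simulate_summary_stats(simulate_panel(cfgb),
                                      cfg_mod(cfgb, gwas_n = 1)), "gwas_n")
})

test_that("estimated effect signs converge to the truth as gwas_n grows", {
  sign_agree <- function(n) {
    cfg <- sim_config(seed = 11, n_variants = 100, n_blocks = 100,
                      n_people_panel = 400, n_causal = 100,
                      effect_sd = 0.02, gwas_n = n)
    ss <- simulate_summary_stats(simulate_panel(cfg), cfg)
    tr <- attr(ss, "truth")
    mean(sign(ss$beta) == sign(tr$true_beta))
  }
  small <- sign_agree(500)
  large <- sign_agree(5e6)
  expect_gt(large, small)
  expect_gt(large, 0.97)
})

test_that("catalog entries are sub-5e-7 and carry block ground truth", {
  st <- tiny_setup()
  catalog <- simulate_catalog(st$summary, st$cfg)
  expect_true(all(catalog$p < 5e-7))
  expect_equal(nrow(catalog), st$cfg$n_disease_loci)
  truth <- attr(catalog, "truth")
  expect_identical(truth$variant_id, catalog$variant_id)
  # empty catalog when no disease loci requested
  cfg0 <- cfg_mod(st$cfg, n_disease_loci = 0L)
  expect_equal(nrow(simulate_catalog(st$summary, cfg0)), 0L)
  cfg_big <- cfg_mod(st$cfg, n_disease_loci = 10000L)
  expect_error(simulate_catalog(st$summary, cfg_big), "exceeds")
})

test_that("WBC cohort tracks the generative score effect; zero effect
          gives zero correlation", {
  cfg <- sim_config(seed = 21, n_variants = 10, n_blocks = 10,
                    n_people_panel = 4000, n_causal = 0, n_disease_loci = 0)
  panel <- simulate_panel(cfg)
  score <- with_seed(33, as.vector(scale(rnorm(4000))))
  co <- simulate_cohorts(panel, score, cfg)
  med <- person_summary(co$wbc$observations)
  idx <- match(med$person_id, co$wbc$persons$person_id)
  r <- partial_cor(score[idx], med$median_wbc,
                   co$wbc$persons[idx, c("age", "sex")])
  expect_lt(abs(r - 0.29), 0.03)

  cfg0 <- cfg_mod(cfg, score_effect = 0)
  co0 <- simulate_cohorts(panel, score, cfg0)
  med0 <- person_summary(co0$wbc$observations)
  r0 <- cor(score[match(med0$person_id, panel$persons)], med0$median_wbc)
  expect_lt(abs(r0), 0.05)

  # counts come at clinical granularity with assay bounds attached
  expect_true(all(co$wbc$observations$count %% 100 == 0))
  expect_true(all(co$wbc$observations$assay_lower <
                    co$wbc$observations$assay_upper))
})

test_that("biopsy outcome is independent of the score by construction", {
  cfg <- sim_config(seed = 22, n_variants = 10, n_blocks = 10,
                    n_people_panel = 8000, n_causal = 0, n_biopsy = 8000L)
  panel <- simulate_panel(cfg)
  score <- with_seed(34, as.vector(scale(rnorm(8000))))
  bio <- simulate_cohorts(panel, score, cfg)$biopsy
  r <- cor(bio$score, bio$outcome == "abnormal")
  expect_lt(abs(r), 0.04)
  # but biopsy-time WBC is lower in pathology cases
  expect_lt(median(bio$wbc_at_biopsy[bio$outcome == "abnormal"]),
            median(bio$wbc_at_biopsy[bio$outcome == "normal"]))
})

test_that("binary-outcome generator hits its target rate and log-OR", {
  score <- with_seed(35, as.vector(scale(rnorm(20000))))
  y <- simulate_binary_outcome(score, log_or = -0.55, rate = 0.053,
                               seed = 36)
  expect_lt(abs(mean(y) - 0.053), 0.005)
  fit <- logistic_fit(y, score)
  expect_gt(exp(-0.55), fit$ci[1])
  expect_lt(exp(-0.55), fit$ci[2])
})
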