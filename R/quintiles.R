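# Residual-disease-signal diagnostics: effect-size quintile sub-scores,
# phenome association scans, permutation and binomial enrichment tests.

#' Split a score model into effect-size quintiles
#'
#' Variants are ranked by absolute weight (ties broken by variant id, so
#' equal weights fill quintiles deterministically from the lower ranks
#' up) and cut at the 20/40/60/80th percentile ranks; quintile sizes
#' differ by at most one.  Quintile 4 thus holds the variants in the
#' 60th-80th percentile of effect-size magnitude.
#'
#' @param model A `pgs_model` with at least 5 variants.
#' @return A list of 5 `pgs_model` objects (attribute `"quintile"` set
#'   to 1..5), whose variant sets partition the input model's.
#' @export
quintile_split <- function(model) {
  stopifnot(inherits(model, "pgs_model"))
  n <- nrow(model$variants)
  if (n < 5L) stop_config("quintile_split: need at least 5 variants, have %d", n)
  ord <- order(abs(model$variants$weight), model$variants$variant_id)
  hi <- ceiling(seq_len(5) * n / 5)
  lo <- c(0L, hi[-5]) + 1L
  lapply(1:5, function(q) {
    sub <- model
    sub$variants <- model$variants[ord[lo[q]:hi[q]], , drop = FALSE]
    rownames(sub$variants) <- NULL
    sub$exclusions <- new_exclusion_log()
    sub$standardization <- c(mean = NA_real_, sd = NA_real_)
    attr(sub, "quintile") <- q
    sub
  })
}

# Logistic association of a binary outcome with one exposure, adjusted
# for covariates, by direct IRLS on the design matrix (much faster than
# the glm() formula interface for repeated scans).  Returns estimate,
# standard error and Wald p for the exposure, or NULL when the fit is
# unusable (non-convergence or separation-sized standard errors).
fast_logistic <- function(y, x, zmat) {
  X <- cbind(zmat, x = x)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  k <- ncol(X)
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  se <- sqrt(diag(cov))[k]
  b <- coef(fit)[k]
  if (!is.finite(se) || se > 50) return(NULL)   # separation guard
  list(coef = b, se = se, p = 2 * pnorm(-abs(b / se)))
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1,
                                         dimnames = list(NULL, "(Intercept)")))
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  stats::model.matrix(~ ., data = covariates)
}

#' Phenome association scan of a score
#'
#' Fits one multivariable logistic regression per phenotype (outcome ~
#' score + covariates) and reports the odds ratio per score s.d., Wald
#' 95% CI and p, direction, and a nominal (`p < 0.05`) flag.  Phenotypes
#' whose fit fails (constant outcome, separation, non-convergence) are
#' returned marked unestimable rather than dropped.
#'
#' @param scores Standardized score vector.
#' @param phenotypes Data frame (or matrix) of binary 0/1 outcome
#'   columns, rows aligned with `scores`.
#' @param covariates Optional covariate data frame.
#' @return Data frame: `phenotype`, `or`, `ci_lo`, `ci_hi`, `p`,
#'   `direction` (`"positive"`/`"inverse"`), `nominal`, `estimable`.
#' @export
phenome_scan <- function(scores, phenotypes, covariates = NULL) {
  phenotypes <- as.data.frame(phenotypes)
  stopifnot(nrow(phenotypes) == length(scores))
  zmat <- covariate_matrix(covariates, length(scores))
  rows <- lapply(names(phenotypes), function(ph) {
    y <- phenotypes[[ph]]
    if (length(unique(y[!is.na(y)])) < 2L) {
      return(data.frame(phenotype = ph, or = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        direction = NA_character_, nominal = FALSE,
                        estimable = FALSE, stringsAsFactors = FALSE))
    }
    f <- fast_logistic(y, scores, zmat)
    if (is.null(f)) {
      return(data.frame(phenotype = ph, or = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        direction = NA_character_, nominal = FALSE,
                        estimable = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(phenotype = ph, or = exp(f$coef),
               ci_lo = exp(f$coef - 1.96 * f$se),
               ci_hi = exp(f$coef + 1.96 * f$se), p = f$p,
               direction = if (f$coef >= 0) "positive" else "inverse",
               nominal = f$p < 0.05, estimable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Rao score test of adding each column of `xs` to a fitted null logistic
# model (y ~ covariates).  Returns the chi-square p-value and the sign
# of the score statistic for every column, in one pass of linear
# algebra; numerically close to the Wald p of the full fit and exactly
# exchangeable across candidate score vectors, which is what the
# permutation machinery needs.
score_test_batch <- function(y, xs, zmat) {
  fit0 <- suppressWarnings(glm.fit(zmat, y, family = binomial()))
  mu <- fit0$fitted.values
  w <- mu * (1 - mu)
  ZtWZ <- crossprod(zmat * sqrt(w))
  ZtWZ_inv <- solve(ZtWZ)
  U <- crossprod(xs, y - mu)                       # k x 1
  A <- crossprod(xs, zmat * w)                     # k x p
  V <- colSums(w * xs^2) - rowSums((A %*% ZtWZ_inv) * A)
  V <- pmax(V, 1e-12)
  stat <- as.vector(U)^2 / V
  list(p = pchisq(stat, df = 1, lower.tail = FALSE),
       sign = sign(as.vector(U)))
}

count_nominal <- function(p, sgn, direction) {
  nominal <- p < 0.05
  if (direction == "positive") sum(nominal & sgn > 0)
  else sum(nominal)
}

#' Permutation test for excess phenotype associations of a quintile score
#'
#' The observed statistic is the number of phenotypes nominally
#' associated (`p < 0.05`) with the quintile sub-score (positive
#' direction only, by default).  The null distribution resamples
#' same-size variant subsets from the full model, re-scores and re-scans
#' them; the empirical p uses the add-one rule
#' `(1 + #{perm >= observed}) / (n_perm + 1)`, which never returns 0.
#' A person-label permutation mode (`mode = "person"`) is provided as an
#' alternative null that preserves the score's construction but breaks
#' the score-phenotype link.
#'
#' Association p-values use the Rao score test of adding the score to a
#' covariates-only logistic model (`test = "score"`, the default, fitted
#' once per phenotype and shared across all permutations) or a full
#' Wald logistic fit per permutation (`test = "wald"`, slower).
#'
#' @param model The full `pgs_model`.
#' @param quintile Which quintile (1..5) to test.
#' @param panel A `genotype_panel` for re-scoring.
#' @param phenotypes Binary outcome data frame, rows = panel persons.
#' @param covariates Optional covariate data frame.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the resampling.
#' @param direction `"positive"` (default) counts positive-direction
#'   nominal associations only; `"any"` counts both directions.
#' @param mode `"variant"` (default) or `"person"`.
#' @param test `"score"` or `"wald"`.
#' @param max_fits Compute cap on `(n_perm + 1) * n_phenotypes`; larger
#'   requests are refused with guidance.
#' @return A list: `observed` (nominal count), `p` (empirical),
#'   `perm_counts`, `quintile`, `n_perm`.
#' @export
permutation_count_test <- function(model, quintile, panel, phenotypes,
                                   covariates = NULL, n_perm = 1000L,
                                   seed = 1L,
                                   direction = c("positive", "any"),
                                   mode = c("variant", "person"),
                                   test = c("score", "wald"),
                                   max_fits = 5e6) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  test <- match.arg(test)
  if (n_perm < 1L) stop_config("n_perm must be >= 1")
  phenotypes <- as.data.frame(phenotypes)
  n_ph <- ncol(phenotypes)
  if ((n_perm + 1) * n_ph > max_fits) {
    stop_config(paste("permutation_count_test: (n_perm+1) x n_phenotypes =",
                      "%g exceeds max_fits = %g; lower n_perm or raise",
                      "max_fits"), (n_perm + 1) * n_ph, max_fits)
  }
  quint <- quintile_split(model)[[quintile]]
  n_q <- nrow(quint$variants)
  obs_score <- as.vector(scale(pgs_score(panel, quint)))
  n <- length(obs_score)
  stopifnot(nrow(phenotypes) == n)
  zmat <- covariate_matrix(covariates, n)

  perm_scores <- with_seed(seed, {
    if (mode == "variant") {
      all_v <- model$variants
      vapply(seq_len(n_perm), function(b) {
        sub <- quint
        sub$variants <- all_v[sample.int(nrow(all_v), n_q), , drop = FALSE]
        as.vector(scale(pgs_score(panel, sub)))
      }, numeric(n))
    } else {
      vapply(seq_len(n_perm), function(b) obs_score[sample.int(n)],
             numeric(n))
    }
  })
  xs <- cbind(obs_score, perm_scores)

  counts <- integer(n_perm + 1)
  if (test == "score") {
    for (ph in seq_len(n_ph)) {
      y <- phenotypes[[ph]]
      st <- score_test_batch(y, xs, zmat)
      nominal <- st$p < 0.05
      if (direction == "positive") nominal <- nominal & st$sign > 0
      counts <- counts + nominal
    }
  } else {
    for (b in seq_len(n_perm + 1)) {
      for (ph in seq_len(n_ph)) {
        f <- fast_logistic(phenotypes[[ph]], xs[, b], zmat)
        if (!is.null(f) && f$p < 0.05 &&
            (direction == "any" || f$coef > 0)) {
          counts[b] <- counts[b] + 1L
        }
      }
    }
  }
  observed <- unname(counts[1])
  perm_counts <- unname(counts[-1])
  list(observed = observed,
       p = (1 + sum(perm_counts >= observed)) / (n_perm + 1),
       perm_counts = perm_counts, quintile = quintile, n_perm = n_perm)
}

#' Per-variant binomial enrichment within a quintile
#'
#' For each phenotype, counts the quintile's variants whose
#' single-variant logistic association (dosage + covariates) is nominal
#' (`p < 0.05`) and computes the exact binomial tail probability
#' `P(X >= k)`, `X ~ Binomial(n_q, 0.05)`, by direct summation of the
#' binomial mass.
#'
#' @param quintile_model One element of [quintile_split()].
#' @param panel A `genotype_panel`.
#' @param phenotypes Binary outcome data frame, rows = panel persons.
#' @param covariates Optional covariate data frame.
#' @return A list: `results` (data frame `phenotype`, `n_snps`,
#'   `k_nominal`, `binom_p`, `enriched`) and `n_enriched` (tally of
#'   phenotypes with tail p < 0.05).
#' @export
per_snp_binomial <- function(quintile_model, panel, phenotypes,
                             covariates = NULL) {
  stopifnot(inherits(quintile_model, "pgs_model"))
  phenotypes <- as.data.frame(phenotypes)
  dos <- panel_dosages(panel, quintile_model$variants$variant_id)
  n_q <- ncol(dos)
  zmat <- covariate_matrix(covariates, nrow(phenotypes))
  res <- lapply(names(phenotypes), function(ph) {
    y <- phenotypes[[ph]]
    ps <- vapply(seq_len(n_q), function(j) {
      f <- fast_logistic(y, dos[, j], zmat)
      if (is.null(f)) NA_real_ else f$p
    }, numeric(1))
    k <- sum(ps < 0.05, na.rm = TRUE)
    bp <- binom_tail(k, n_q, 0.05)
    data.frame(phenotype = ph, n_snps = n_q, k_nominal = k, binom_p = bp,
               enriched = bp < 0.05, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  list(results = res, n_enriched = sum(res$enriched))
}

#' Exact binomial tail probability P(X >= k)
#'
#' Direct summation of `dbinom(k:n, n, prob)`; `k = 0` gives 1.
#'
#' @param k Observed count.
#' @param n Number of trials.
#' @param prob Success probability (default 0.05).
#' @return The upper-tail probability.
#' @export
binom_tail <- function(k, n, prob = 0.05) {
  stopifnot(k >= 0, k <= n)
  if (k == 0) return(1)
  sum(dbinom(k:n, n, prob))
}
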