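# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards.  All generators route their randomness through this
# so that a config seed yields bit-identical output regardless of the
# surrounding RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic sub-seed from a master seed and a stage label.
# Keeps results reproducible when stages are re-run in isolation; the
# result always fits a 32-bit signed integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483647) + 1L
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' Partial correlation of two variables given covariates
#'
#' Correlation between the residuals of `x` and `y` after least-squares
#' adjustment of each on the covariate matrix.  With no covariates (or
#' constant covariates) this reduces to the plain Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional data frame or matrix of adjustment
#'   covariates (one row per element of `x`).
#' @return A single correlation in `[-1, 1]`.
#' @examples
#' x <- rnorm(50); z <- rnorm(50); y <- x + z + rnorm(50)
#' partial_cor(x, y, data.frame(z = z))
#' @export
partial_cor <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(x))
    ok <- ok & stats::complete.cases(covariates)
  }
  if (sum(ok) < 3L) {
    stop_config("partial_cor: fewer than 3 complete cases (%d)", sum(ok))
  }
  x <- x[ok]; y <- y[ok]
  if (is.null(covariates)) return(cor(x, y))
  z <- stats::model.matrix(~ ., data = covariates[ok, , drop = FALSE])
  # drop constant columns beyond the intercept to avoid rank problems
  keep <- c(TRUE, apply(z[, -1, drop = FALSE], 2, function(v) sd(v) > 0))
  z <- z[, keep, drop = FALSE]
  rx <- stats::lm.fit(z, x)$residuals
  ry <- stats::lm.fit(z, y)$residuals
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop_config("partial_cor: zero residual variance after adjustment")
  }
  cor(rx, ry)
}

# Pearson correlation between dosage columns that treats a zero-variance
# column as uncorrelated with everything (monomorphic variants carry no
# LD information).
dosage_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

# Squared dosage correlation matrix for a set of columns, with
# zero-variance columns mapped to r2 = 0 off the diagonal.
dosage_r2_matrix <- function(m) {
  s <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))
  r[!is.finite(r)] <- 0
  r[s == 0, ] <- 0
  r[, s == 0] <- 0
  diag(r) <- 1
  r ^ 2
}
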