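# Genotype-informed WBC reference machinery: per-person summaries,
# assay-outlier flags, sliding-window percentile curves, 2.5th-percentile
# classification and stratified summaries.
#
# Quantile convention throughout: linear interpolation between order
# statistics (stats::quantile type 7).

#' Per-person median and minimum WBC count
#'
#' Counts above `cap` (default 35,000 cells/uL, values that likely
#' reflect an active disease process) are excluded before summarizing.
#' Persons left with no surviving observation are dropped and reported
#' in the `"dropped"` attribute.
#'
#' @param observations Data frame with `person_id` and `count`
#'   (cells/uL); one row per measurement.
#' @param cap Exclusion threshold in cells/uL.
#' @return Data frame: `person_id`, `n_used`, `median_wbc`, `min_wbc`
#'   (even-length medians are the mean of the middle two values).
#' @examples
#' obs <- data.frame(person_id = "a", count = c(4000, 36000, 8000))
#' person_summary(obs)   # median 6000, min 4000; 36000 excluded
#' @export
person_summary <- function(observations, cap = 35000) {
  stopifnot(all(c("person_id", "count") %in% names(observations)))
  if (any(observations$count <= 0, na.rm = TRUE)) {
    stop_config("person_summary: non-positive counts present")
  }
  keep <- observations$count <= cap
  all_ids <- unique(observations$person_id)
  surv <- observations[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(split(surv$count, surv$person_id), function(x)
    data.frame(n_used = length(x), median_wbc = median(x), min_wbc = min(x))))
  out <- data.frame(person_id = rownames(out), out, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[match(intersect(all_ids, out$person_id), out$person_id), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- setdiff(all_ids, out$person_id)
  out
}

#' Flag persons with any count below their assay's lower bound
#'
#' A person is an outlier when at least one surviving measurement is
#' strictly below the reference lower bound of the assay that produced
#' it (a count exactly at the bound is not an outlier).
#'
#' @param observations Data frame with `person_id`, `count`,
#'   `assay_lower`.
#' @param cap Count cap applied before flagging (as in
#'   [person_summary()]).
#' @return Data frame: `person_id`, `outlier` (logical).
#' @export
outlier_flag <- function(observations, cap = 35000) {
  need <- c("person_id", "count", "assay_lower")
  stopifnot(all(need %in% names(observations)))
  if (anyNA(observations$assay_lower)) {
    stop_config("outlier_flag: missing assay lower bound in %d row(s)",
                sum(is.na(observations$assay_lower)))
  }
  surv <- observations[observations$count <= cap, , drop = FALSE]
  low <- tapply(surv$count < surv$assay_lower, surv$person_id, any)
  data.frame(person_id = names(low), outlier = as.vector(low),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sliding-window percentiles of a value across the score range
#'
#' At each grid point `g`, persons with `|score - g| <= half_width`
#' contribute their value, and the requested percentiles (default 5th,
#' 50th, 95th) are computed within the window.  Grid points whose
#' window holds fewer than `min_n` persons are omitted and listed in
#' the `"omitted"` attribute.
#'
#' @param scores Standardized scores (one per person).
#' @param values The value summarized (e.g. median WBC count).
#' @param half_width Window half-width in score s.d. (default 0.2).
#' @param grid Grid of score values; default: the observed score range
#'   in steps of 0.1.
#' @param min_n Minimum window occupancy (default 20).
#' @param probs Percentiles to report.
#' @return Data frame: `score`, `p5`, `p50`, `p95` (named after
#'   `probs`), `n_in_window`.
#' @export
window_percentiles <- function(scores, values, half_width = 0.2,
                               grid = NULL, min_n = 20,
                               probs = c(0.05, 0.5, 0.95)) {
  stopifnot(length(scores) == length(values))
  ok <- is.finite(scores) & is.finite(values)
  scores <- scores[ok]; values <- values[ok]
  if (length(scores) == 0L) stop_config("window_percentiles: empty input")
  if (is.null(grid)) {
    grid <- seq(ceiling(min(scores) * 10) / 10,
                floor(max(scores) * 10) / 10, by = 0.1)
  }
  rows <- lapply(grid, function(g) {
    inw <- abs(scores - g) <= half_width
    n <- sum(inw)
    if (n < min_n) return(NULL)
    q <- quantile(values[inw], probs = probs, type = 7, names = FALSE)
    out <- data.frame(score = g, t(q), n_in_window = n)
    names(out)[2:(1 + length(probs))] <- paste0("p", probs * 100)
    out
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  if (is.null(out)) {
    stop_config("window_percentiles: no grid point reaches min_n = %d", min_n)
  }
  rownames(out) <- NULL
  attr(out, "omitted") <- grid[!keep]
  out
}

#' Classify biopsy counts against a genotype-informed reference range
#'
#' For each biopsied person, the reference window holds the WBC-cohort
#' members whose score lies within `half_width` of the person's score;
#' the person's threshold is the `percentile` quantile (default 2.5th)
#' of the window members' lowest observed WBC counts, and the person is
#' within range when their biopsy-time count is at or above the
#' threshold (`rule = "geq"`, the default; `rule = "gt"` requires
#' strictly above).  Windows below `min_n` members leave the person
#' unclassifiable (`classifiable = FALSE`) rather than silently out of
#' range.
#'
#' @param biopsy Data frame with `person_id`, `score`, `wbc_at_biopsy`.
#' @param cohort_scores Standardized scores of the reference (WBC)
#'   cohort.
#' @param cohort_min_wbc Lowest observed WBC count per reference-cohort
#'   member, aligned with `cohort_scores`.
#' @param half_width Window half-width in score s.d. (default 0.2).
#' @param percentile Window quantile defining the threshold (default
#'   0.025).
#' @param min_n Minimum window occupancy (default 20).
#' @param rule `"geq"` (at or above the threshold counts as within
#'   range) or `"gt"`.
#' @return Data frame: `person_id`, `threshold`, `n_in_window`,
#'   `within_range`, `classifiable`.
#' @export
classify_within_range <- function(biopsy, cohort_scores, cohort_min_wbc,
                                  half_width = 0.2, percentile = 0.025,
                                  min_n = 20, rule = c("geq", "gt")) {
  rule <- match.arg(rule)
  stopifnot(all(c("person_id", "score", "wbc_at_biopsy") %in% names(biopsy)),
            length(cohort_scores) == length(cohort_min_wbc))
  if (any(biopsy$wbc_at_biopsy <= 0)) {
    stop_config("classify_within_range: non-positive biopsy counts")
  }
  rows <- lapply(seq_len(nrow(biopsy)), function(i) {
    inw <- abs(cohort_scores - biopsy$score[i]) <= half_width
    n <- sum(inw)
    if (n < min_n) {
      return(data.frame(person_id = biopsy$person_id[i],
                        threshold = NA_real_, n_in_window = n,
                        within_range = NA, classifiable = FALSE,
                        stringsAsFactors = FALSE))
    }
    thr <- quantile(cohort_min_wbc[inw], probs = percentile, type = 7,
                    names = FALSE)
    within <- if (rule == "geq") biopsy$wbc_at_biopsy[i] >= thr
              else biopsy$wbc_at_biopsy[i] > thr
    data.frame(person_id = biopsy$person_id[i], threshold = thr,
               n_in_window = n, within_range = within, classifiable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified summary of genotype-informed classification
#'
#' Tallies classified biopsies by outcome and biopsy-count stratum:
#' total in stratum, number within the genotype-informed range, and the
#' percentage (one decimal).  Strata are half-open `(lo, hi]` intervals;
#' biopsies outside every stratum (e.g. counts above 4000 cells/uL,
#' which are within normal ranges by standard thresholds) and
#' unclassifiable ones are excluded from the table.
#'
#' @param classified Data frame with `outcome`, `wbc_at_biopsy`,
#'   `within_range` (e.g. the fixture biopsy table merged with
#'   [classify_within_range()] output).
#' @param breaks Stratum boundaries in cells/uL; default
#'   `c(0, 2500, 3000, 3500, 4000)` giving four `(lo, hi]` strata.
#' @return Data frame: `outcome`, `lo`, `hi`, `n`, `n_within`, `pct`
#'   (percentage within, one decimal, `NA` for empty strata).
#' @export
stratified_summary <- function(classified,
                               breaks = c(0, 2500, 3000, 3500, 4000)) {
  need <- c("outcome", "wbc_at_biopsy", "within_range")
  stopifnot(all(need %in% names(classified)))
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop_config("stratified_summary: breaks must be strictly increasing (disjoint strata)")
  }
  ok <- !is.na(classified$within_range)
  x <- classified[ok, , drop = FALSE]
  grid <- expand.grid(outcome = unique(classified$outcome),
                      stratum = seq_len(length(breaks) - 1),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$stratum[i]
    lo <- breaks[s]; hi <- breaks[s + 1]
    inx <- x$outcome == grid$outcome[i] &
      x$wbc_at_biopsy > lo & x$wbc_at_biopsy <= hi
    n <- sum(inx)
    nw <- sum(x$within_range[inx])
    data.frame(outcome = grid$outcome[i], lo = lo, hi = hi, n = n,
               n_within = nw,
               pct = if (n > 0) round(100 * nw / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$outcome, out$lo), ]
  rownames(out) <- NULL
  out
}
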