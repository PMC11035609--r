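#' Deterministic biopsy-classification fixture
#'
#' Builds, without any randomness, a biopsy cohort plus a matching WBC
#' reference cohort whose genotype-informed classification reproduces a
#' fixed stratified summary: among normal-outcome biopsies, 100% of
#' counts in (3500, 4000], 9/13 (69.2%) in (3000, 3500], 1/18 (5.6%) in
#' (2500, 3000] and 0/18 in (0, 2500] fall within the genotype-informed
#' range; among abnormal-outcome biopsies only the (3500, 4000] stratum
#' (3/3) does.
#'
#' Each biopsied person is given a score 1 s.d. away from every other,
#' so the +/-0.2 s.d. windows are disjoint, and a private window cohort
#' of 40 members whose lowest observed counts all equal the intended
#' 2.5th-percentile threshold -- 200 cells/uL below the biopsy count
#' when the person should classify within range, 200 above otherwise.
#'
#' @param half_width Window half-width in score s.d. the fixture is
#'   built for (default 0.2).
#' @return A list with `biopsy` (person_id, score, wbc_at_biopsy,
#'   outcome), `cohort` (person_id, score, min_wbc), `expected` (the
#'   per-stratum tallies the classification must reproduce), and
#'   `half_width`.
#' @examples
#' fx <- biopsy_fixture()
#' cls <- classify_within_range(fx$biopsy, fx$cohort$score,
#'                              fx$cohort$min_wbc)
#' stratified_summary(merge(fx$biopsy, cls))
#' @export
biopsy_fixture <- function(half_width = 0.2) {
  cells <- data.frame(
    outcome = rep(c("normal", "abnormal"), each = 4),
    lo = rep(c(0, 2500, 3000, 3500), 2),
    hi = rep(c(2500, 3000, 3500, 4000), 2),
    n = c(18, 18, 13, 10, 10, 2, 6, 3),
    n_within = c(0, 1, 9, 10, 0, 0, 0, 3),
    stringsAsFactors = FALSE
  )
  mid <- c(`2500` = 2000, `3000` = 2800, `3500` = 3200, `4000` = 3800)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    k <- cells$n[i]
    if (k == 0) return(NULL)
    data.frame(outcome = cells$outcome[i],
               wbc_at_biopsy = rep(mid[[as.character(cells$hi[i])]], k),
               within = seq_len(k) <= cells$n_within[i],
               stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  biopsy <- data.frame(person_id = sprintf("B%03d", seq_len(n)),
                       score = as.numeric(seq_len(n)),
                       wbc_at_biopsy = rows$wbc_at_biopsy,
                       outcome = rows$outcome, stringsAsFactors = FALSE)
  # 40 window members per biopsy, all sharing the intended threshold
  thr <- ifelse(rows$within, rows$wbc_at_biopsy - 200,
                rows$wbc_at_biopsy + 200)
  offs <- seq(-half_width / 2, half_width / 2, length.out = 40)
  cohort <- data.frame(
    person_id = sprintf("C%03d_%02d", rep(seq_len(n), each = 40),
                        rep(1:40, n)),
    score = rep(biopsy$score, each = 40) + rep(offs, n),
    min_wbc = rep(thr, each = 40), stringsAsFactors = FALSE)
  expected <- cells
  expected$pct <- ifelse(cells$n > 0,
                         round(100 * cells$n_within / cells$n, 1), NA_real_)
  list(biopsy = biopsy, cohort = cohort, expected = expected,
       half_width = half_width)
}
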