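# Diagnostic scoring: the published combined NASH score, its cutoff, and the
# CPA-based fibrosis bands; plus the per-grade summary table.

.check_pct <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0 | x > 100))
    .hq_stop(sprintf("%s must lie in [0, 100]", what), "hq_domain_error")
}

#' Combined NASH score from the three H&E percentages
#'
#' `score = 0.058 * fat% + 0.079 * ballooning% + 0.485 * inflammation% - 3.882`
#' with the published logistic-regression coefficients (configurable under
#' `cfg$scoring`). Strictly increasing in each argument.
#'
#' @param fat_pct,ballooning_pct,inflammation_pct percentages in `[0, 100]`.
#' @param cfg configuration from [hq_config()].
#' @return numeric score (vectorized).
#' @export
combined_nash_score <- function(fat_pct, ballooning_pct, inflammation_pct,
                                cfg = hq_config()) {
  .check_pct(fat_pct, "fat_pct")
  .check_pct(ballooning_pct, "ballooning_pct")
  .check_pct(inflammation_pct, "inflammation_pct")
  s <- cfg$scoring
  s$w_fat * fat_pct + s$w_ballooning * ballooning_pct +
    s$w_inflammation * inflammation_pct + s$intercept
}

#' NASH call from the combined score
#'
#' Positive iff the score reaches the published cutoff (0.31); the boundary is
#' inclusive.
#'
#' @param score combined score from [combined_nash_score()].
#' @param cfg configuration from [hq_config()].
#' @return logical (vectorized).
#' @export
classify_nash <- function(score, cfg = hq_config()) score >= cfg$scoring$nash_cutoff

#' Fibrosis band from the collagen proportionate area
#'
#' Highest published cutoff met, boundaries inclusive: CPA below 2.05% gives
#' `"<F2"`, `[2.05, 3.1)` gives `"F2"`, `[3.1, 8.1)` gives `"F3"`, and 8.1% or
#' above gives `"F4"`.
#'
#' @param cpa_pct CPA percentage in `[0, 100]`.
#' @param cfg configuration from [hq_config()].
#' @return factor with levels `<F2`, `F2`, `F3`, `F4` (vectorized).
#' @export
fibrosis_band_from_cpa <- function(cpa_pct, cfg = hq_config()) {
  .check_pct(cpa_pct, "cpa_pct")
  co <- cfg$scoring$cpa_cutoffs
  if (any(diff(co) <= 0)) .hq_stop("cpa_cutoffs must be strictly increasing", "hq_config_error")
  cut(cpa_pct, breaks = c(-Inf, co, Inf), labels = c("<F2", "F2", "F3", "F4"),
      right = FALSE)
}

#' Semiquantitative NASH CRN score record
#'
#' @param steatosis_grade integer 0-3.
#' @param lobular_inflammation integer 0-3.
#' @param ballooning integer 0-2.
#' @param fibrosis_stage one of `"0","1","1a","1b","1c","2","3","4"` (numeric
#'   accepted).
#' @param case_id identifier.
#' @return one-row data.frame including the NAS (sum of the first three).
#' @export
crn_score <- function(steatosis_grade, lobular_inflammation, ballooning,
                      fibrosis_stage, case_id = "case") {
  if (!steatosis_grade %in% 0:3) .hq_stop("steatosis_grade must be 0-3", "hq_domain_error")
  if (!lobular_inflammation %in% 0:3) .hq_stop("lobular_inflammation must be 0-3", "hq_domain_error")
  if (!ballooning %in% 0:2) .hq_stop("ballooning must be 0-2", "hq_domain_error")
  fibrosis_stage <- as.character(fibrosis_stage)
  if (!fibrosis_stage %in% c("0", "1", "1a", "1b", "1c", "2", "3", "4"))
    .hq_stop("fibrosis_stage must be one of 0,1,1a,1b,1c,2,3,4", "hq_domain_error")
  data.frame(case_id = case_id, steatosis_grade = steatosis_grade,
             lobular_inflammation = lobular_inflammation, ballooning = ballooning,
             fibrosis_stage = fibrosis_stage,
             nas = steatosis_grade + lobular_inflammation + ballooning)
}

#' Median and IQR of quantitative values per semiquantitative category
#'
#' For each quantitative feature and each category of the matching CRN scale,
#' reports n, median and the interquartile range (quartiles by linear
#' interpolation between order statistics, R quantile type 7). Categories with
#' no cases are omitted.
#'
#' @param results data.frame with `case_id` and any of `fat_pct`,
#'   `inflammation_pct`, `ballooning_pct`, `cpa_pct` (e.g. stacked
#'   [quantify()]/[compute_cpa()] output, see [as.data.frame.quant_result()]).
#' @param scores data.frame with `case_id` and the CRN columns
#'   `steatosis_grade`, `lobular_inflammation`, `ballooning`, `fibrosis_stage`.
#' @return data.frame with columns `feature`, `scale`, `category`, `n`,
#'   `median`, `q1`, `q3`.
#' @export
summarize_by_grade <- function(results, scores) {
  if (nrow(results) != nrow(scores))
    .hq_stop("results and scores must be case-matched (equal length)", "hq_pairing_error")
  if (!is.null(results$case_id) && !is.null(scores$case_id)) {
    ord <- match(results$case_id, scores$case_id)
    if (any(is.na(ord))) .hq_stop("case_id mismatch between results and scores", "hq_pairing_error")
    scores <- scores[ord, , drop = FALSE]
  }
  pairs <- list(c("fat_pct", "steatosis_grade"),
                c("inflammation_pct", "lobular_inflammation"),
                c("ballooning_pct", "ballooning"),
                c("cpa_pct", "fibrosis_stage"))
  rows <- list()
  for (pr in pairs) {
    if (is.null(results[[pr[1L]]]) || is.null(scores[[pr[2L]]])) next
    v <- results[[pr[1L]]]; g <- as.character(scores[[pr[2L]]])
    ok <- is.finite(v) & !is.na(g)
    for (cat in sort(unique(g[ok]))) {
      x <- v[ok & g == cat]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = pr[1L], scale = pr[2L], category = cat, n = length(x),
        median = q[2L], q1 = q[1L], q3 = q[3L])
    }
  }
  do.call(rbind, rows)
}

#' @export
as.data.frame.quant_result <- function(x, ...) {
  data.frame(case_id = x$case_id, fat_pct = x$fat_pct,
             inflammation_pct = x$inflammation_pct,
             ballooning_pct = x$ballooning_pct, cpa_pct = x$cpa_pct,
             tissue_area_px = x$tissue_area_px)
}
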