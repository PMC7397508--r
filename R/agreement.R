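# Validation statistics: intraclass correlation, ordered-trend test, ROC with
# Youden cutoff, observer agreement (weighted kappa), and paired-biopsy deltas.

#' Intraclass correlation ICC(2,1), absolute agreement
#'
#' Two-way random-effects model, absolute agreement, single measure
#' (Shrout-Fleiss ICC(2,1)); the 95% CI uses the standard F-distribution
#' bounds (McGraw-Wong). Absolute agreement penalizes a constant shift between
#' raters, unlike consistency variants.
#'
#' @param x numeric vector of ratings by the first rater, or an n x k matrix of
#'   ratings (n subjects, k raters).
#' @param y ratings by the second rater when `x` is a vector.
#' @return list with `icc`, `ci` (95%), `p`, `n`, `k`, `model`.
#' @export
icc_agreement <- function(x, y = NULL) {
  r <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  if (!all(is.finite(r))) .hq_stop("ratings must be finite", "hq_domain_error")
  n <- nrow(r); k <- ncol(r)
  if (n < 3L || k < 2L) .hq_stop("need at least 3 subjects and 2 raters", "hq_domain_error")
  gm <- mean(r)
  if (sum((r - gm)^2) == 0) .hq_stop("ratings have zero variance", "hq_degenerate_error")
  SSr <- k * sum((rowMeans(r) - gm)^2)
  SSc <- n * sum((colMeans(r) - gm)^2)
  SSe <- sum((r - gm)^2) - SSr - SSc
  MSr <- SSr / (n - 1); MSc <- SSc / (k - 1); MSe <- SSe / ((n - 1) * (k - 1))
  icc <- (MSr - MSe) / (MSr + (k - 1) * MSe + (k / n) * (MSc - MSe))
  if (MSe <= .Machine$double.eps * max(MSr, MSc)) {
    # no residual variance: F-based interval collapses onto the estimate
    return(list(icc = icc, ci = c(icc, icc), p = 0, n = n, k = k,
                model = "ICC(2,1): two-way random, absolute agreement, single measure"))
  }
  alpha <- 0.05
  Fv <- MSr / MSe
  p <- stats::pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  Fj <- MSc / MSe
  vn <- (k - 1) * (n - 1) * (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * Fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lb <- n * (MSr - FL * MSe) / (FL * (k * MSc + (k * n - k - n) * MSe) + n * MSr)
  ub <- n * (FU * MSr - MSe) / (k * MSc + (k * n - k - n) * MSe + n * FU * MSr)
  list(icc = icc, ci = c(lb, ub), p = p, n = n, k = k,
       model = "ICC(2,1): two-way random, absolute agreement, single measure")
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' The JT statistic is the sum of pairwise Mann-Whitney counts over ordered
#' group pairs (ties count 1/2). The z value uses the tie-corrected normal
#' approximation. When the total sample size is at most 20 and there are no
#' ties, the exact null distribution is computed as the convolution of
#' Mann-Whitney U distributions (J decomposes into independent U statistics of
#' each group against all earlier groups combined); the `method` field records
#' which p-value is reported.
#'
#' @param groups list of numeric vectors in hypothesized increasing order
#'   (at least 3 nonempty groups).
#' @param alternative `"two.sided"` (default) or `"increasing"` (one-sided,
#'   the ordered alternative).
#' @return list with `statistic` (J), `z`, `p`, `method`, `n`.
#' @export
jonckheere_terpstra <- function(groups, alternative = c("two.sided", "increasing")) {
  alternative <- match.arg(alternative)
  if (!is.list(groups) || length(groups) < 3L)
    .hq_stop("need at least 3 ordered groups", "hq_domain_error")
  if (any(vapply(groups, length, 0L) == 0L))
    .hq_stop("all groups must be nonempty", "hq_domain_error")
  ng <- vapply(groups, length, 0L)
  x <- unlist(groups)
  N <- length(x)
  J <- 0
  kk <- length(groups)
  for (i in seq_len(kk - 1L)) for (j in (i + 1L):kk) {
    for (xi in groups[[i]]) J <- J + sum(groups[[j]] > xi) + 0.5 * sum(groups[[j]] == xi)
  }
  tie <- table(x)
  if (length(tie) == 1L)
    return(list(statistic = J, z = 0, p = 1, method = "degenerate", n = N))
  mu <- (N^2 - sum(ng^2)) / 4
  t1 <- as.numeric(tie)
  A <- N * (N - 1) * (2 * N + 5) - sum(ng * (ng - 1) * (2 * ng + 5)) -
    sum(t1 * (t1 - 1) * (2 * t1 + 5))
  B <- sum(ng * (ng - 1) * (ng - 2)) * sum(t1 * (t1 - 1) * (t1 - 2))
  C <- sum(ng * (ng - 1)) * sum(t1 * (t1 - 1))
  v <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C / (8 * N * (N - 1))
  z <- (J - mu) / sqrt(v)
  no_ties <- all(tie == 1L)
  if (N <= 20L && no_ties) {
    pmf <- .jt_null_pmf(ng)
    # J takes integer values without ties
    p_ge <- sum(pmf[(round(J) + 1L):length(pmf)])
    p_le <- sum(pmf[1:(round(J) + 1L)])
    p <- if (alternative == "increasing") p_ge else min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    # continuity-corrected z for the p-value; the reported z stays raw
    zc <- sign(J - mu) * max(abs(J - mu) - 0.5, 0) / sqrt(v)
    p <- if (alternative == "increasing") stats::pnorm(zc, lower.tail = FALSE)
         else 2 * stats::pnorm(-abs(zc))
    method <- "normal"
  }
  list(statistic = J, z = z, p = p, method = method, n = N)
}

# Exact null pmf of J for tie-free data: convolution over groups of the
# Mann-Whitney U distribution of group j against groups 1..j-1 combined.
.jt_null_pmf <- function(ng) {
  pmf <- 1
  m <- ng[1L]
  for (j in 2:length(ng)) {
    n <- ng[j]
    u <- stats::dwilcox(0:(m * n), m, n)
    pmf <- stats::convolve(pmf, rev(u), type = "open")
    m <- m + n
  }
  pmax(pmf, 0)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Builds the full ROC curve (positives are values at or above a cutoff),
#' computes the AUROC by trapezoidal integration (equal to the Mann-Whitney
#' identity, ties handled by half-counts), a DeLong 95% CI, and the cutoff
#' maximizing Youden J = sensitivity + specificity - 1 using the
#' midpoint-between-observed-values convention (lowest such midpoint on ties).
#'
#' @param values numeric marker values (higher = more likely positive).
#' @param labels binary labels (0/1, logical, or 2-level factor).
#' @return list with `auroc`, `ci`, `best_cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(values, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(values) != length(labels)) .hq_stop("length mismatch", "hq_domain_error")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    .hq_stop("both classes must be present", "hq_domain_error")
  uv <- sort(unique(values))
  cuts <- c(-Inf, (uv[-1L] + uv[-length(uv)]) / 2, Inf)
  sens <- vapply(cuts, function(ct) sum(values >= ct & labels == 1L) / n_pos, 0)
  spec <- vapply(cuts, function(ct) sum(values < ct & labels == 0L) / n_neg, 0)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auroc <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(ord)]) / 2)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(
    pROC::roc(response = labels, predictor = values, levels = c(0, 1),
              direction = "<", quiet = TRUE), method = "delong")))[c(1L, 3L)]
  finite <- is.finite(cuts)
  J <- sens + spec - 1
  Jf <- J[finite]
  best_i <- which(finite)[which(Jf == max(Jf))[1L]]
  ct <- cuts[best_i]
  tp <- sum(values >= ct & labels == 1L); fp <- sum(values >= ct & labels == 0L)
  fn <- n_pos - tp; tn <- n_neg - fp
  list(auroc = auroc, ci = ci, best_cutoff = ct,
       sensitivity = tp / n_pos, specificity = tn / n_neg,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       n_pos = n_pos, n_neg = n_neg)
}

#' Cohen's kappa between two raters
#'
#' @param x,y rating vectors on a common (ordinal) scale.
#' @param weight `"unweighted"` or `"quadratic"` (for ordinal scales).
#' @return numeric kappa.
#' @export
cohen_kappa <- function(x, y, weight = c("unweighted", "quadratic")) {
  weight <- match.arg(weight)
  lev <- sort(unique(c(x, y)))
  k <- length(lev)
  if (k < 2L) .hq_stop("ratings are constant", "hq_degenerate_error")
  tab <- table(factor(x, levels = lev), factor(y, levels = lev))
  p <- tab / sum(tab)
  w <- if (weight == "quadratic") {
    1 - (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2
  } else diag(k)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  (po - pe) / (1 - pe)
}

#' Inter-observer agreement across a rating matrix
#'
#' For ordinal scales, quadratic-weighted kappa for every observer pair (the
#' unweighted value is reported alongside); for continuous measurements,
#' ICC(2,1) across all observers.
#'
#' @param ratings matrix with cases in rows and observers in columns (at least
#'   3 cases and 2 observers).
#' @param scale `"ordinal_kappa"` or `"icc"`.
#' @return for kappa: list with `pairs` (data.frame of pairwise kappas),
#'   `mean_kappa`, `mean_kappa_unweighted`; for icc: the [icc_agreement()]
#'   result.
#' @export
observer_agreement <- function(ratings, scale = c("ordinal_kappa", "icc")) {
  scale <- match.arg(scale)
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 3L || ncol(ratings) < 2L)
    .hq_stop("need at least 3 cases and 2 observers", "hq_domain_error")
  if (length(unique(as.vector(ratings))) < 2L)
    .hq_stop("ratings are constant", "hq_degenerate_error")
  if (scale == "icc") return(icc_agreement(ratings))
  no <- ncol(ratings)
  rows <- list()
  for (i in seq_len(no - 1L)) for (j in (i + 1L):no) {
    rows[[length(rows) + 1L]] <- data.frame(
      obs_a = i, obs_b = j,
      kappa_quadratic = cohen_kappa(ratings[, i], ratings[, j], "quadratic"),
      kappa_unweighted = cohen_kappa(ratings[, i], ratings[, j], "unweighted"))
  }
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, mean_kappa = mean(pairs$kappa_quadratic),
       mean_kappa_unweighted = mean(pairs$kappa_unweighted))
}

#' Paired-biopsy deltas with Wilcoxon signed-rank tests
#'
#' For each feature, the per-case delta is `after - before`; the median delta
#' and a Wilcoxon signed-rank p-value are reported (exact when n <= 25 and no
#' zeros/ties, by the R default; zero differences are discarded, the standard
#' zero-discard rule). All-zero differences give p = 1 by convention.
#'
#' @param before,after data.frames with `case_id` and feature columns; rows are
#'   matched by `case_id`.
#' @param features feature columns to compare.
#' @param alternative passed to [stats::wilcox.test()].
#' @return data.frame with `feature`, `n`, `median_delta`, `p`.
#' @export
paired_delta <- function(before, after,
                         features = c("fat_pct", "inflammation_pct",
                                      "ballooning_pct", "cpa_pct"),
                         alternative = "two.sided") {
  if (nrow(before) < 3L) .hq_stop("need at least 3 pairs", "hq_domain_error")
  if (nrow(before) != nrow(after) ||
      !setequal(before$case_id, after$case_id))
    .hq_stop("before/after case ids do not match", "hq_pairing_error")
  after <- after[match(before$case_id, after$case_id), , drop = FALSE]
  rows <- list()
  for (f in features) {
    if (is.null(before[[f]]) || is.null(after[[f]])) next
    d <- after[[f]] - before[[f]]
    ok <- is.finite(d)
    d <- d[ok]
    if (length(d) == 0L) next
    p <- if (all(d == 0)) 1 else suppressWarnings(
      stats::wilcox.test(d, alternative = alternative)$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, n = length(d), median_delta = stats::median(d), p = p)
  }
  do.call(rbind, rows)
}
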