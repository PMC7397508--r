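test_that("ICC(2,1) matches an aov-based oracle and penalizes constant shifts", {
  r <- icc_agreement(1:5, 1:5)
  expect_identical(r$icc, 1)
  expect_identical(r$ci, c(1, 1))

  shifted <- icc_agreement(1:5, 2:6)
  # oracle: two-way ANOVA mean squares -> Shrout-Fleiss ICC(2,1)
  df <- data.frame(v = c(1:5, 2:6), subj = factor(rep(1:5, 2)),
                   rater = factor(rep(1:2, each = 5)))
  a <- suppressWarnings(stats::anova(stats::aov(v ~ subj + rater, df)))
  MSr <- a["subj", "Mean Sq"]; MSc <- a["rater", "Mean Sq"]
  MSe <- a["Residuals", "Mean Sq"]
  oracle <- (MSr - MSe) / (MSr + MSe + (2 / 5) * (MSc - MSe))
  expect_equal(shifted$icc, oracle, tolerance = 1e-12)
  expect_lt(shifted$icc, 1)

  # noisy ratings: CI brackets the estimate
  set.seed(4)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.3)
  ry <- icc_agreement(x, y)
  expect_lte(ry$ci[1], ry$icc)
  expect_gte(ry$ci[2], ry$icc)

  # independent ratings: ICC near zero
  set.seed(7)
  r0 <- icc_agreement(rnorm(1000), rnorm(1000))
  expect_lt(abs(r0$icc), 0.1)

  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), class = "hq_degenerate_error")
  expect_error(icc_agreement(1:2, 1:2), class = "hq_domain_error")
})

# brute-force JT oracle: enumerate every assignment of the pooled values to
# the group layout and tabulate the statistic
jt_brute_p <- function(groups, observed) {
  x <- unlist(groups)
  ng <- vapply(groups, length, 0L)
  stat <- function(gs) {
    J <- 0
    for (i in 1:(length(gs) - 1)) for (j in (i + 1):length(gs))
      for (xi in gs[[i]]) J <- J + sum(gs[[j]] > xi) + 0.5 * sum(gs[[j]] == xi)
    J
  }
  idx_all <- seq_along(x)
  vals <- c()
  for (a in utils::combn(idx_all, ng[1], simplify = FALSE)) {
    rest <- setdiff(idx_all, a)
    for (b in utils::combn(rest, ng[2], simplify = FALSE)) {
      cc <- setdiff(rest, b)
      vals <- c(vals, stat(list(x[a], x[b], x[cc])))
    }
  }
  mean(vals >= observed - 1e-9)
}

test_that("Jonckheere-Terpstra matches full-enumeration oracles and is antisymmetric", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  jt <- jonckheere_terpstra(g, alternative = "increasing")
  expect_identical(jt$statistic, 12)     # maximal: all 12 ordered pairs concordant
  expect_equal(jt$p, 1 / 90, tolerance = 1e-12)
  expect_identical(jt$method, "exact")

  set.seed(11)
  for (i in 1:3) {
    gr <- list(rnorm(2), rnorm(2), rnorm(2))
    jr <- jonckheere_terpstra(gr, alternative = "increasing")
    expect_equal(jr$p, jt_brute_p(gr, jr$statistic), tolerance = 1e-9)
  }

  # reversing the group order negates z
  set.seed(3)
  gg <- list(rnorm(4), rnorm(4) + 1, rnorm(4) + 2)
  j1 <- jonckheere_terpstra(gg)
  j2 <- jonckheere_terpstra(rev(gg))
  expect_equal(j2$z, -j1$z, tolerance = 1e-9)

  # degenerate constant input
  jd <- jonckheere_terpstra(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_identical(jd$z, 0)
  expect_identical(jd$p, 1)
  expect_identical(jd$method, "degenerate")

  # ties force the normal approximation
  jtied <- jonckheere_terpstra(list(c(1, 1, 2), c(2, 3, 3), c(3, 4, 4)))
  expect_identical(jtied$method, "normal")

  expect_error(jonckheere_terpstra(list(1:3, 4:6)), class = "hq_domain_error")
})

test_that("ROC analysis matches the Mann-Whitney identity and hand-enumerated curves", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_identical(r$auroc, 1)
  expect_identical(r$best_cutoff, 2.5)
  expect_identical(c(r$sensitivity, r$specificity), c(1, 1))

  # Mann-Whitney identity on random data, including ties
  set.seed(21)
  for (i in 1:10) {
    v <- sample(1:8, 40, replace = TRUE)
    l <- rbinom(40, 1, 0.4)
    if (length(unique(l)) < 2) next
    r2 <- roc_analysis(v, l)
    rk <- rank(v)
    mw <- (sum(rk[l == 1]) - sum(l) * (sum(l) + 1) / 2) / (sum(l) * sum(1 - l))
    expect_equal(r2$auroc, mw, tolerance = 1e-12)
    expect_lte(r2$ci[1], r2$auroc + 1e-12)
    expect_gte(r2$ci[2], r2$auroc - 1e-12)
  }

  # label-independent values: AUROC near 0.5
  set.seed(5)
  rn <- roc_analysis(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(rn$auroc - 0.5), 0.05)

  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), class = "hq_domain_error")
})

test_that("kappa reproduces hand-computed agreement and the null is centred at zero", {
  expect_identical(cohen_kappa(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0), "quadratic"), 1)
  # 2x2 agreement table ((20,5),(10,15)): Po=0.7, Pe=0.5, kappa=0.4
  x <- rep(c(0, 0, 1, 1), c(20, 5, 10, 15))
  y <- rep(c(0, 1, 0, 1), c(20, 5, 10, 15))
  expect_equal(cohen_kappa(x, y, "unweighted"), 0.4, tolerance = 1e-12)

  set.seed(9)
  k0 <- cohen_kappa(sample(0:3, 500, TRUE), sample(0:3, 500, TRUE), "unweighted")
  expect_lt(abs(k0), 0.1)

  ratings <- cbind(c(0, 1, 2, 3, 1, 2), c(0, 1, 2, 3, 1, 2), c(0, 1, 2, 3, 2, 2))
  oa <- observer_agreement(ratings, "ordinal_kappa")
  expect_identical(nrow(oa$pairs), 3L)
  expect_identical(oa$pairs$kappa_quadratic[1], 1)
  expect_true(oa$mean_kappa <= 1 && oa$mean_kappa > 0.5)

  oi <- observer_agreement(matrix(rnorm(30), 10, 3), "icc")
  expect_true(is.numeric(oi$icc))
  expect_error(observer_agreement(matrix(1, 5, 2), "ordinal_kappa"),
               class = "hq_degenerate_error")
})

test_that("paired deltas report medians and exact sign-rank p-values", {
  before <- data.frame(case_id = sprintf("c%d", 1:6), fat_pct = c(3, 7, 11, 15, 19, 23))
  same <- paired_delta(before, before, features = "fat_pct")
  expect_identical(same$median_delta, 0)
  expect_identical(same$p, 1)

  # constant +2 shift: the median delta is exactly +2
  after2 <- before; after2$fat_pct <- before$fat_pct + 2
  d2 <- paired_delta(before, after2, features = "fat_pct")
  expect_identical(d2$median_delta, 2)

  # distinct all-positive deltas, n = 6: exact one-sided p is
  # P(all six signs positive) = 2^-6 = 1/64 (sign-rank enumeration)
  after3 <- before; after3$fat_pct <- before$fat_pct + c(1.5, 2.2, 1.8, 2.5, 2.0, 2.4)
  d3 <- paired_delta(before, after3, features = "fat_pct", alternative = "greater")
  expect_equal(d3$p, 1 / 64, tolerance = 1e-12)

  bad <- before; bad$case_id[1] <- "zz"
  expect_error(paired_delta(before, bad), class = "hq_pairing_error")
})
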