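# helper: half-background / half-tissue image with a matching label mask,
# a linearly separable two-class problem by construction
two_class_case <- function(n = 256L) {
  h <- matrix(0, n, n); e <- matrix(0, n, n)
  right <- (n / 2 + 1):n
  h[, right] <- 0.10
  e[, right] <- 0.60
  img <- hne_from_densities(h, e)
  lm <- matrix(1L, n, n)
  lm[, right] <- 2L
  structure(lm, classes = c("background", "tissue_other"),
            class = c("label_mask", "matrix", "array"))
  list(image = img,
       labels = structure(lm, classes = c("background", "tissue_other"),
                          class = c("label_mask", "matrix", "array")))
}

test_that("tile features behave as documented on uniform and structured input", {
  white <- rgb_image(array(255, c(64L, 64L, 3L)), "HE")
  ft <- extract_features(white, tile_px = 8L)
  expect_identical(nrow(ft), 64L)
  expect_true(all(ft$bright_frac == 1))
  expect_lt(max(ft$h_mean), 0.01)
  expect_lt(max(ft$e_mean), 0.01)

  tr <- fixture_hne_mid()
  f1 <- extract_features(tr$image, tile_px = 8L)
  f2 <- extract_features(tr$image, tile_px = 8L)
  expect_identical(f1, f2)

  # a tile inside a fat vacuole vs a tile inside an inflammatory focus
  lm <- label_mask_from_truth(tr)
  labs <- tile_labels(lm, 8L, 0.99)
  fat_tile <- which(labs == "fat")[1]
  foc_tile <- which(labs == "inflammation")[1]
  expect_gt(f1$bright_frac[fat_tile], f1$bright_frac[foc_tile])
  expect_lt(f1$h_mean[fat_tile], f1$h_mean[foc_tile])

  expect_error(extract_features(white, tile_px = 4L), class = "hq_param_error")
})

test_that("training validates class support and names offending classes", {
  cs <- two_class_case()
  # a third class with too few tiles
  lm <- cs$labels
  lm[1:8, 1:24] <- 3L
  attr(lm, "classes") <- c("background", "tissue_other", "fat")
  err <- expect_error(train_region_model(list(cs$image), list(lm), seed = 1),
                      class = "hq_training_error")
  expect_match(conditionMessage(err), "fat")

  one <- cs$labels
  one[, ] <- 2L
  expect_error(train_region_model(list(cs$image), list(one), seed = 1),
               class = "hq_training_error")
})

test_that("a separable two-class problem is learned almost perfectly and reproducibly", {
  cs <- two_class_case()
  m1 <- train_region_model(list(cs$image), list(cs$labels), seed = 17)
  expect_gte(m1$training_meta$holdout_accuracy, 0.99)
  m2 <- train_region_model(list(cs$image), list(cs$labels), seed = 17)
  p1 <- predict_map(m1, cs$image)
  p2 <- predict_map(m2, cs$image)
  expect_identical(p1$prob, p2$prob)

  # probabilities sum to 1 at every pixel
  sums <- apply(p1$prob, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)

  # argmax agrees with the construction away from the boundary
  cm <- classify_map(p1)
  cls <- attr(cm, "classes")
  expect_identical(cls[cm[100, 40]], "background")
  expect_identical(cls[cm[100, 200]], "tissue_other")

  # feature-version mismatch is refused
  cfg2 <- hq_config(overrides = list(classifier = list(feature_version = "hqfeat-2")))
  expect_error(predict_map(m1, cs$image, cfg = cfg2), class = "hq_compat_error")
})

test_that("an all-background image gets high background probability everywhere", {
  cs <- two_class_case()
  m <- train_region_model(list(cs$image), list(cs$labels), seed = 17)
  white <- rgb_image(array(255, c(64L, 64L, 3L)), "HE")
  pm <- predict_map(m, white)
  bg <- hepaquant:::.class_prob(pm, "background")
  expect_true(all(bg >= 0.9))
})

test_that("shuffling balanced tile labels drops held-out accuracy to chance", {
  cs <- two_class_case()
  # permute 8-px label tiles relative to the image (labels stay balanced)
  lm <- cs$labels
  n_t <- 256L / 8L
  set.seed(99)
  perm <- sample(n_t * n_t)
  shuffled <- lm
  k <- 0L
  for (j in seq_len(n_t)) for (i in seq_len(n_t)) {
    k <- k + 1L
    src <- perm[k]
    si <- (src - 1L) %% n_t; sj <- (src - 1L) %/% n_t
    shuffled[((i - 1L) * 8L + 1L):(i * 8L), ((j - 1L) * 8L + 1L):(j * 8L)] <-
      lm[(si * 8L + 1L):((si + 1L) * 8L), (sj * 8L + 1L):((sj + 1L) * 8L)]
  }
  m <- train_region_model(list(cs$image), list(shuffled), seed = 17)
  expect_lt(abs(m$training_meta$holdout_accuracy - 0.5), 0.1)
})
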