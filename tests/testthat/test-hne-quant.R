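test_that("fat segmentation finds circular vacuoles and respects the shape filter", {
  tr <- generate_hne(synth_params(image_px = c(384L, 384L), n_vacuoles = 12L,
                                  fat_r = c(8, 8), seed = 21))
  img <- tr$image
  tis <- compute_tissue_mask(img)
  fat <- segment_fat(img, tis)
  lab <- hepaquant:::.label_mask(fat)
  expect_identical(max(lab), 12L)
  expect_lt(abs(sum(fat) - 12 * pi * 64) / (12 * pi * 64), 0.10)

  # add a large irregular tear (thin white band, circularity far below 0.55),
  # placed in a band clear of the vacuoles so it cannot merge with one
  cc <- 40:340
  clear <- vapply(20:350, function(r0) {
    band <- (r0 - 3):(r0 + 12)
    all(tr$masks$tissue[band, cc]) && !any(tr$masks$fat[band, cc])
  }, TRUE)
  r0 <- (20:350)[which(clear)[1]]
  rr <- r0:(r0 + 9)
  px <- img$pixels
  for (ch in 1:3) px[rr, cc, ch] <- 255
  img2 <- rgb_image(px, "HE")
  tis2 <- compute_tissue_mask(img2)
  fat2 <- segment_fat(img2, tis2)
  lab2 <- hepaquant:::.label_mask(fat2)
  expect_identical(max(lab2), 12L)     # tear excluded, vacuoles kept
  expect_false(any(fat2[rr, cc]))
})

test_that("images without white holes give an empty fat mask; empty tissue errors", {
  tr <- generate_hne(synth_params(image_px = c(256L, 256L), seed = 5))
  tis <- compute_tissue_mask(tr$image)
  expect_identical(sum(segment_fat(tr$image, tis)), 0L)
  empty <- binary_mask(matrix(FALSE, 256L, 256L))
  expect_error(segment_fat(tr$image, empty), class = "hq_precondition_error")
})

test_that("inflammation fallback recovers dense nuclear foci and ignores sparse nuclei", {
  tr <- fixture_hne_mid()
  tis <- compute_tissue_mask(tr$image)
  infl <- segment_inflammation(tr$image, tis)
  est <- 100 * sum(infl & tis) / sum(tis)
  expect_lt(abs(est - 100 * tr$realized[["inflammation"]]), 1.5)

  # scattered sparse nuclei only
  plain <- generate_hne(synth_params(image_px = c(256L, 256L), seed = 5))
  tisp <- compute_tissue_mask(plain$image)
  ip <- segment_inflammation(plain$image, tisp)
  expect_lt(100 * sum(ip) / sum(tisp), 0.5)

  # blank tissue, no nuclei at all
  blank <- blank_tissue_image()
  tisb <- compute_tissue_mask(blank)
  expect_identical(sum(segment_inflammation(blank, tisb)), 0L)
})

test_that("ballooning fallback recovers pale nucleated cells and excludes fat", {
  tr <- generate_hne(synth_params(image_px = c(256L, 256L), n_balloon_cells = 5L,
                                  balloon_r = c(14.1, 14.1), seed = 9))
  tis <- compute_tissue_mask(tr$image)
  ball <- segment_ballooning(tr$image, tis)
  est <- 100 * sum(ball & tis) / sum(tis)
  expect_lt(abs(est - 100 * tr$realized[["ballooning"]]), 2)

  # fat-only image: ballooning near zero and disjoint from the fat mask
  fo <- generate_hne(synth_params(image_px = c(256L, 256L),
                                  target_fat_frac = 0.15, seed = 13))
  tisf <- compute_tissue_mask(fo$image)
  fatf <- segment_fat(fo$image, tisf)
  ballf <- segment_ballooning(fo$image, tisf, fat = fatf)
  expect_identical(sum(ballf & fatf), 0L)
  expect_lt(100 * sum(ballf) / sum(tisf), 1)

  blank <- blank_tissue_image()
  tisb <- compute_tissue_mask(blank)
  expect_identical(sum(segment_ballooning(blank, tisb)), 0L)
})

test_that("quantify computes exact percentages with fat > inflammation > ballooning priority", {
  tis <- binary_mask(matrix(TRUE, 100L, 100L))
  mk <- function(n_px, offset = 0L) {
    m <- matrix(FALSE, 100L, 100L)
    m[seq_len(n_px) + offset] <- TRUE
    binary_mask(m)
  }
  q <- quantify(list(fat = mk(300L)), tis)
  expect_identical(q$fat_pct, 3)
  expect_identical(round(q$fat_pct, 2), 3.00)

  q0 <- quantify(list(), tis)
  expect_identical(c(q0$fat_pct, q0$inflammation_pct, q0$ballooning_pct), c(0, 0, 0))

  # 100 px fat and 100 px ballooning overlapping by 40 px
  q2 <- quantify(list(fat = mk(100L), ballooning = mk(100L, offset = 60L)), tis)
  expect_identical(q2$fat_pct, 1)
  expect_identical(q2$ballooning_pct, 0.6)

  expect_error(quantify(list(fat = mk(10L)), binary_mask(matrix(FALSE, 100L, 100L))),
               class = "hq_precondition_error")
})

test_that("feature percentages are disjoint, bounded, and deterministic", {
  tr <- fixture_hne_mid()
  img <- tr$image
  tis <- compute_tissue_mask(img)
  run <- function() {
    fat <- segment_fat(img, tis)
    infl <- segment_inflammation(img, tis)
    ball <- segment_ballooning(img, tis, fat = fat)
    quantify(list(fat = fat, inflammation = infl, ballooning = ball), tis)
  }
  q1 <- run(); q2 <- run()
  expect_identical(q1, q2)
  expect_lte(q1$fat_pct + q1$inflammation_pct + q1$ballooning_pct, 100)
})
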