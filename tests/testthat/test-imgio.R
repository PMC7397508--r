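test_that("PNG and TIFF round-trips preserve pixels; grayscale is rejected", {
  set.seed(1)
  px <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64L, 64L, 3L))
  img <- rgb_image(px, stain_kind = "HE")

  fp <- withr::local_tempfile(fileext = ".png")
  write_image(img, fp)
  back <- load_image(fp, stain_kind = "HE")
  expect_identical(back$pixels, img$pixels + 0)
  expect_identical(back$stain_kind, "HE")

  ft <- withr::local_tempfile(fileext = ".tif")
  write_image(img, ft)
  expect_identical(load_image(ft)$pixels, img$pixels + 0)

  fg <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 64, 64), fg)
  err <- expect_error(load_image(fg), class = "hq_format_error")
  expect_match(conditionMessage(err), "1 channel")
})

test_that("synthetic images round-trip byte-exactly through PNG", {
  tr <- fixture_hne_mid()
  fp <- withr::local_tempfile(fileext = ".png")
  write_image(tr$image, fp)
  expect_identical(load_image(fp, "HE")$pixels, tr$image$pixels)
})

test_that("tissue mask matches blob coverage, errors on blank slides, and is border-invariant", {
  white <- rgb_image(array(255, c(64L, 64L, 3L)))
  expect_error(compute_tissue_mask(white), class = "hq_no_tissue_error")

  tr <- fixture_hne_mid()
  tis <- compute_tissue_mask(tr$image)
  HW <- prod(dim(tis))
  # generator targets 60% coverage; mask area within 2% of 0.60 * H * W
  expect_lt(abs(sum(tis) - 0.60 * HW), 0.02 * 0.60 * HW)
  # vacuole holes are retained as tissue: truth tissue is recovered near-exactly
  expect_lt(mean(xor(tis, tr$masks$tissue)), 0.002)

  # adding a 10-px white border leaves the tissue area unchanged
  d <- dim(tr$image$pixels)
  padded <- array(255, c(d[1] + 20L, d[2] + 20L, 3L))
  padded[11:(10 + d[1]), 11:(10 + d[2]), ] <- tr$image$pixels
  tis2 <- compute_tissue_mask(rgb_image(padded, "HE"))
  expect_identical(sum(tis2), sum(tis))
})

test_that("rasterization uses half-open pixel coverage, last-wins overlaps, and bounds checks", {
  sq <- function(x0, y0, x1, y1, cls) list(
    xy = cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)), class = cls)

  ann <- annotation_set(list(sq(10, 10, 20, 20, "fat")))
  lm <- rasterize_annotations(ann, c(64L, 64L))
  expect_identical(sum(lm == match("fat", attr(lm, "classes"))), 100L)

  empty <- rasterize_annotations(annotation_set(), c(64L, 64L))
  expect_true(all(empty == 1L))
  expect_identical(attr(empty, "classes")[1], "background")

  ann2 <- annotation_set(list(sq(10, 10, 20, 20, "fat"),
                              sq(15, 15, 25, 25, "inflammation")))
  lm2 <- rasterize_annotations(ann2, c(64L, 64L))
  cls <- attr(lm2, "classes")
  expect_identical(cls[lm2[18, 18]], "inflammation")  # overlap: last drawn wins
  expect_identical(cls[lm2[12, 12]], "fat")
  expect_identical(sum(lm2 == match("fat", cls)), 100L - 25L)

  bad <- annotation_set(list(sq(-1, 10, 20, 20, "fat")))
  err <- expect_error(rasterize_annotations(bad, c(64L, 64L)),
                      class = "hq_annotation_error")
  expect_match(conditionMessage(err), "region 1")
})

test_that("rasterize after vectorize is the identity on axis-aligned rectangles", {
  mask <- matrix(FALSE, 64L, 64L)
  mask[5:20, 8:30] <- TRUE
  mask[40:60, 45:50] <- TRUE
  ann <- polygons_from_mask(mask, class = "fat")
  lm <- rasterize_annotations(ann, dim(mask))
  expect_identical(lm == match("fat", attr(lm, "classes")), unname(mask))
})

test_that("GeoJSON annotations round-trip", {
  ann <- annotation_set(list(
    list(xy = cbind(x = c(10, 30, 30, 10), y = c(10, 10, 25, 25)),
         class = "fat", annotator = "rater1"),
    list(xy = cbind(x = c(40, 55, 47), y = c(40, 40, 55)),
         class = "inflammation", annotator = "rater2")))
  fp <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(ann, fp)
  back <- read_annotations(fp)
  expect_length(back$regions, 2L)
  expect_identical(back$regions[[2]]$class, "inflammation")
  expect_equal(back$regions[[1]]$xy, ann$regions[[1]]$xy, ignore_attr = TRUE)
  lm1 <- rasterize_annotations(ann, c(64L, 64L))
  lm2 <- rasterize_annotations(back, c(64L, 64L))
  expect_identical(unclass(lm1), unclass(lm2))
})

test_that("masks survive a PNG round-trip", {
  tr <- fixture_hne_mid()
  fp <- withr::local_tempfile(fileext = ".png")
  write_mask_png(tr$masks$fat, fp)
  expect_identical(unname(unclass(read_mask_png(fp, "fat"))),
                   unname(unclass(tr$masks$fat)))
})
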