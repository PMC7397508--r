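test_that("generation is deterministic for a fixed seed", {
  p <- synth_params(image_px = c(256L, 256L), target_fat_frac = 0.10,
                    target_inflam_frac = 0.02, target_balloon_frac = 0.08, seed = 77)
  a <- generate_hne(p); b <- generate_hne(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$masks, b$masks)

  ps <- synth_params(image_px = c(256L, 256L), target_cpa_frac = 0.05, seed = 77)
  s1 <- generate_sirius_red(ps); s2 <- generate_sirius_red(ps)
  expect_identical(s1$image$pixels, s2$image$pixels)
})

test_that("realized fractions hit their targets within tolerance", {
  tr <- generate_hne(synth_params(image_px = c(512L, 512L),
                                  target_fat_frac = 0.15, seed = 7))
  expect_gte(tr$realized[["fat"]], 0.12)
  expect_lte(tr$realized[["fat"]], 0.18)
  expect_identical(dim(tr$masks$fat), dim(tr$image$pixels)[1:2])

  sr <- generate_sirius_red(synth_params(image_px = c(512L, 512L),
                                         target_cpa_frac = 0.13, seed = 3))
  expect_gte(sr$realized[["cpa"]], 0.10)
  expect_lte(sr$realized[["cpa"]], 0.16)
})

test_that("zero targets give empty truth masks and plain tissue", {
  tr <- generate_hne(synth_params(image_px = c(256L, 256L), seed = 5))
  expect_identical(sum(tr$masks$fat), 0L)
  expect_identical(sum(tr$masks$inflammation), 0L)
  expect_identical(sum(tr$masks$ballooning), 0L)
  expect_gt(sum(tr$masks$tissue), 0L)

  sr <- generate_sirius_red(synth_params(image_px = c(256L, 256L),
                                         target_cpa_frac = 0, seed = 5))
  expect_identical(sum(sr$masks$collagen), 0L)
})

test_that("truth-mask classes are pairwise disjoint and inside tissue", {
  for (seed in c(2, 12)) {
    tr <- generate_hne(synth_params(image_px = c(256L, 256L),
                                    target_fat_frac = 0.12, target_inflam_frac = 0.03,
                                    target_balloon_frac = 0.10, seed = seed))
    m <- tr$masks
    expect_identical(sum(m$fat & m$inflammation), 0L)
    expect_identical(sum(m$fat & m$ballooning), 0L)
    expect_identical(sum(m$inflammation & m$ballooning), 0L)
    expect_identical(sum(m$fat & !m$tissue), 0L)
  }
})

test_that("capsules hug the tissue boundary and are flagged structural in truth", {
  sr <- fixture_sr_struct()
  st <- sr$masks$structural
  expect_gt(sum(st), 0L)
  band <- sr$masks$tissue & !hepaquant:::.erode(sr$masks$tissue, 20L)
  expect_gt(sum(st & band), 0L)  # capsule pixels sit in the boundary band
})

test_that("parameter validation rejects bad inputs", {
  expect_error(synth_params(target_fat_frac = 0.7, seed = 1), class = "hq_param_error")
  expect_error(synth_params(target_fat_frac = 0.4, target_balloon_frac = 0.4,
                            target_inflam_frac = 0.2, seed = 1),
               class = "hq_param_error")
  expect_error(synth_params(), class = "hq_param_error")
  expect_error(generate_cohort(6, grade_mix = c(0.5, 0.5, 0.5), seed = 1),
               class = "hq_param_error")
})

test_that("cohorts stratify correctly, order severity, and are seed-stable", {
  coh <- generate_cohort(6, seed = 5, image_px = c(384L, 384L), include_sr = FALSE)
  expect_length(coh, 6L)
  expect_identical(vapply(coh, `[[`, 0L, "stratum"), rep(1:3, each = 2L))
  fat <- vapply(coh, function(cs) cs$hne$realized[["fat"]], 0)
  med <- tapply(fat, rep(1:3, each = 2L), stats::median)
  expect_true(all(diff(med) > 0))
  nas <- vapply(coh, function(cs) cs$crn$nas, 0)
  expect_identical(unique(nas[1:2]), 1)
  expect_identical(unique(nas[5:6]), 7)

  coh2 <- generate_cohort(6, seed = 5, image_px = c(384L, 384L), include_sr = FALSE)
  expect_identical(coh2[[3]]$hne$image$pixels, coh[[3]]$hne$image$pixels)
})

test_that("synthetic annotations rasterize close to the truth masks", {
  tr <- generate_hne(synth_params(image_px = c(256L, 256L), n_vacuoles = 8L,
                                  fat_r = c(8, 10), seed = 14))
  ann <- synth_annotations(tr)
  lm <- rasterize_annotations(ann, dim(tr$masks$fat))
  fat_poly <- lm == match("fat", attr(lm, "classes"))
  iou <- sum(fat_poly & tr$masks$fat) / sum(fat_poly | tr$masks$fat)
  expect_gt(iou, 0.85)
})
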