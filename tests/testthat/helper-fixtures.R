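# Shared synthetic fixtures, generated once per test session.

.hq_fixtures <- new.env(parent = emptyenv())

hq_fixture <- function(name, fun) {
  if (!exists(name, envir = .hq_fixtures))
    assign(name, fun(), envir = .hq_fixtures)
  get(name, envir = .hq_fixtures)
}

# mid-severity H&E case, 512^2, all three features present
fixture_hne_mid <- function() hq_fixture("hne_mid", function() {
  generate_hne(synth_params(image_px = c(512L, 512L), target_fat_frac = 0.15,
                            target_inflam_frac = 0.03, target_balloon_frac = 0.10,
                            seed = 7))
})

# Sirius-red case with capsule and vessel rings, 512^2
fixture_sr_struct <- function() hq_fixture("sr_struct", function() {
  generate_sirius_red(synth_params(image_px = c(512L, 512L), target_cpa_frac = 0.13,
                                   include_capsule = TRUE, include_vessels = TRUE,
                                   seed = 3))
})

# build an H&E-coloured image directly from density maps (bypasses the
# generator; used as an independent construction in stain tests)
hne_from_densities <- function(h, e, cfg = hq_config(), quantize = TRUE) {
  M <- hepaquant:::.stain_matrix(cfg)
  px <- array(0, c(nrow(h), ncol(h), 3L))
  for (ch in 1:3) px[, , ch] <- 256 * 10^(-(h * M[ch, 1L] + e * M[ch, 2L])) - 1
  if (quantize) px <- round(px)
  rgb_image(pmin(pmax(px, 0), 255), stain_kind = "HE")
}

# uniform "blank tissue" image: eosin cytoplasm, no nuclei, no lesions
blank_tissue_image <- function(n = 128L) {
  h <- matrix(0.10, n, n)
  e <- matrix(0.60, n, n)
  hne_from_densities(h, e)
}
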