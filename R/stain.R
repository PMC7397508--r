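# Stain separation: optical-density unmixing for H&E and a hue-band collagen
# signal for picrosirius red.

#' Per-channel optical density of an 8-bit image
#'
#' `OD = -log10((I + 1) / 256)`, so a pure-white pixel has OD ~ 0 and a black
#' pixel ~ 2.4.
#'
#' @param pixels H x W x 3 array of 8-bit intensities.
#' @return array of the same shape.
#' @export
rgb_to_od <- function(pixels) -log10((pixels + 1) / 256)

.stain_matrix <- function(cfg) {
  h <- cfg$stains$hematoxylin; h <- h / sqrt(sum(h^2))
  e <- cfg$stains$eosin;       e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  cbind(hematoxylin = h, eosin = e, residual = r)
}

#' Unmix an H&E image into stain-density maps
#'
#' Projects per-pixel optical density onto fixed hematoxylin and eosin unit
#' vectors (Ruifrok-Johnston convention; vectors configurable under
#' `cfg$stains`). Negative projections are clipped to zero.
#'
#' @param image an [rgb_image()] with `stain_kind == "HE"`.
#' @param cfg configuration from [hq_config()].
#' @return object of class `stain_maps` with matrices `hematoxylin`, `eosin`
#'   (clipped, >= 0) and `residual` (signed).
#' @export
unmix_hne <- function(image, cfg = hq_config()) {
  stopifnot(inherits(image, "rgb_image"))
  if (image$stain_kind != "HE")
    .hq_stop(sprintf("expected an HE image, got stain_kind = %s", image$stain_kind),
             "hq_stain_error")
  d <- dim(image$pixels)
  od <- matrix(rgb_to_od(image$pixels), d[1L] * d[2L], 3L)
  M <- .stain_matrix(cfg)
  dens <- od %*% t(solve(M))
  structure(list(
    hematoxylin = matrix(pmax(dens[, 1L], 0), d[1L], d[2L]),
    eosin = matrix(pmax(dens[, 2L], 0), d[1L], d[2L]),
    residual = matrix(dens[, 3L], d[1L], d[2L])
  ), class = "stain_maps")
}

# trapezoidal membership: 1 on [lo, hi], linear ramp of width `ramp` outside
.ramp_membership <- function(x, lo, hi, ramp) {
  pmin(pmax((x - (lo - ramp)) / ramp, 0), 1) * pmin(pmax(((hi + ramp) - x) / ramp, 0), 1)
}

#' Collagen signal of a Sirius-red image
#'
#' Membership of each pixel's HSV colour in the red band: hue within
#' `[sr_hue_lo, sr_hue_hi]` degrees (wrapping through 0 = red), saturation at
#' least `sr_sat_min`, value at least `sr_val_min`, each with a linear ramp at
#' the band edge. The signal is the product of the three memberships, in [0,1].
#'
#' @param image an [rgb_image()] with `stain_kind == "SIRIUS_RED"`.
#' @param cfg configuration from [hq_config()].
#' @return object of class `stain_maps` with matrix `collagen_signal`.
#' @export
collagen_signal_sr <- function(image, cfg = hq_config()) {
  stopifnot(inherits(image, "rgb_image"))
  if (image$stain_kind != "SIRIUS_RED")
    .hq_stop(sprintf("expected a SIRIUS_RED image, got stain_kind = %s", image$stain_kind),
             "hq_stain_error")
  s <- cfg$stains
  px <- image$pixels
  r <- px[, , 1L]; g <- px[, , 2L]; b <- px[, , 3L]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  delta <- mx - mn
  hue <- matrix(0, nrow(r), ncol(r))
  ir <- delta > 0 & mx == r
  ig <- delta > 0 & !ir & mx == g
  ib <- delta > 0 & !ir & !ig
  hue[ir] <- 60 * ((g[ir] - b[ir]) / delta[ir])
  hue[ig] <- 60 * (2 + (b[ig] - r[ig]) / delta[ig])
  hue[ib] <- 60 * (4 + (r[ib] - g[ib]) / delta[ib])
  hue <- ((hue + 180) %% 360) - 180  # wrap to (-180, 180], red at 0
  sat <- ifelse(mx > 0, delta / mx, 0)
  val <- mx / 255
  sig <- .ramp_membership(hue, s$sr_hue_lo, s$sr_hue_hi, s$sr_hue_ramp) *
    pmin(pmax((sat - (s$sr_sat_min - s$sr_sat_ramp)) / s$sr_sat_ramp, 0), 1) *
    pmin(pmax((val - (s$sr_val_min - s$sr_val_ramp)) / s$sr_val_ramp, 0), 1)
  sig[delta == 0] <- 0  # achromatic pixels carry no collagen signal
  structure(list(collagen_signal = sig), class = "stain_maps")
}
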