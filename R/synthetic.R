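# Synthetic histology: parametric H&E-like and Sirius-red-like images with
# exact ground-truth masks. Colours are generated from the configured stain
# vectors so optical-density unmixing is self-consistent, and every feature is
# placed with known geometry, so segmentation, classifier training and the
# validation statistics are all testable without clinical images.

#' Parameters of the synthetic histology generator
#'
#' Either target area fractions (of tissue) or explicit object counts drive
#' each feature class; when a count (`n_vacuoles`, `n_foci`, `n_balloon_cells`,
#' `n_septa`) is given it takes precedence over the corresponding target
#' fraction and the realized-fraction tolerance is not enforced for that class.
#'
#' @param image_px integer `c(H, W)`.
#' @param target_fat_frac,target_inflam_frac,target_balloon_frac,target_cpa_frac
#'   target area fractions of tissue in `[0, 0.6]`.
#' @param n_vacuoles,n_foci,n_balloon_cells,n_septa optional explicit counts.
#' @param fat_r,balloon_r,focus_r radius ranges (pixels) for vacuoles,
#'   ballooned cells and inflammatory foci.
#' @param include_capsule,include_vessels add a capsule arc / vessel rings to
#'   Sirius-red images (flagged structural in the ground truth).
#' @param noise_sd Gaussian pixel noise, 8-bit scale.
#' @param tissue_frac fraction of the frame covered by the tissue blob.
#' @param seed integer seed (mandatory; the generator is fully deterministic
#'   given its parameters).
#' @return a validated list of class `synth_params`.
#' @export
synth_params <- function(image_px = c(768L, 768L),
                         target_fat_frac = 0, target_inflam_frac = 0,
                         target_balloon_frac = 0, target_cpa_frac = 0,
                         n_vacuoles = NULL, n_foci = NULL,
                         n_balloon_cells = NULL, n_septa = NULL,
                         fat_r = c(6, 12), balloon_r = c(11.5, 12),
                         focus_r = c(16, 30),
                         include_capsule = FALSE, include_vessels = FALSE,
                         noise_sd = 4, tissue_frac = 0.60, seed) {
  if (missing(seed) || !is.numeric(seed)) .hq_stop("seed is mandatory", "hq_param_error")
  fr <- c(target_fat_frac, target_inflam_frac, target_balloon_frac, target_cpa_frac)
  if (any(fr < 0 | fr > 0.6)) .hq_stop("target fractions must lie in [0, 0.6]", "hq_param_error")
  if (target_fat_frac + target_inflam_frac + target_balloon_frac > 0.9)
    .hq_stop("target fractions sum above 0.9", "hq_param_error")
  if (any(image_px < 64)) .hq_stop("image must be at least 64 x 64", "hq_param_error")
  structure(list(image_px = as.integer(image_px),
                 target_fat_frac = target_fat_frac,
                 target_inflam_frac = target_inflam_frac,
                 target_balloon_frac = target_balloon_frac,
                 target_cpa_frac = target_cpa_frac,
                 n_vacuoles = n_vacuoles, n_foci = n_foci,
                 n_balloon_cells = n_balloon_cells, n_septa = n_septa,
                 fat_r = fat_r, balloon_r = balloon_r, focus_r = focus_r,
                 include_capsule = include_capsule,
                 include_vessels = include_vessels,
                 noise_sd = noise_sd, tissue_frac = tissue_frac,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# wavy-ellipse tissue blob, radius iterated to hit the target coverage
.tissue_blob <- function(H, W, frac) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  theta <- atan2(rows - cy, cols - cx)
  amp <- stats::runif(4, 0.005, 0.02)
  ph <- stats::runif(4, 0, 2 * pi)
  modwave <- 1
  for (k in 1:4) modwave <- modwave + amp[k] * sin((k + 1) * theta + ph[k])
  dn <- sqrt(((rows - cy) / H)^2 + ((cols - cx) / W)^2)
  r0 <- sqrt(frac / pi)
  cap <- 0.485 / (1 + sum(amp))
  mask <- NULL
  for (i in 1:5) {
    r0 <- min(r0, cap)
    mask <- dn <= r0 * modwave
    a <- sum(mask) / (H * W)
    if (abs(a - frac) / frac < 0.002 || r0 >= cap) break
    r0 <- r0 * sqrt(frac / max(a, 1e-9))
  }
  mask
}

# sequential disc placement on a jittered hexagonal grid; guarantees
# non-overlap for radius <= pitch/2 - jitter
.hex_sites <- function(H, W, eligible, pitch = 28, jitter = 1.5) {
  dy <- round(pitch * sqrt(3) / 2)
  rows <- seq(4, H - 3, by = dy)
  sites <- NULL
  for (k in seq_along(rows)) {
    xs <- seq(if (k %% 2 == 0) 4 + pitch / 2 else 4, W - 3, by = pitch)
    sites <- rbind(sites, cbind(rows[k], xs))
  }
  sites <- sites + matrix(stats::runif(length(sites), -jitter, jitter), nrow(sites), 2L)
  ok <- eligible[cbind(pmin(pmax(round(sites[, 1L]), 1L), H),
                       pmin(pmax(round(sites[, 2L]), 1L), W))]
  sites <- sites[ok, , drop = FALSE]
  sites[sample.int(nrow(sites)), , drop = FALSE]
}

# draw discs at consecutive sites until `target_area` is covered (or `n` discs
# are placed); returns list(mask, centers = cbind(row, col, rad), used)
.fill_sites <- function(H, W, sites, from, r_range, target_area = NULL, n = NULL) {
  mask <- matrix(FALSE, H, W)
  centers <- NULL
  area <- 0
  i <- from
  while (i <= nrow(sites)) {
    if (!is.null(n) && !is.null(centers) && nrow(centers) >= n) break
    if (is.null(n) && (is.null(target_area) || area >= target_area)) break
    rad <- stats::runif(1, r_range[1L], r_range[2L])
    mask <- .add_disc(mask, sites[i, 1L], sites[i, 2L], rad)
    centers <- rbind(centers, c(sites[i, 1L], sites[i, 2L], rad))
    area <- area + .disc_area(rad)
    i <- i + 1L
  }
  if (!is.null(n) && (is.null(centers) || nrow(centers) < n))
    .hq_stop("not enough eligible sites for the requested object count", "hq_generator_error")
  list(mask = mask, centers = centers, next_site = i)
}

# dart-throwing placement for explicit counts with arbitrary radii
.dart_discs <- function(H, W, allowed, n, r_range, min_gap = 4) {
  mask <- matrix(FALSE, H, W)
  centers <- NULL
  idx <- which(allowed)
  if (length(idx) == 0L) .hq_stop("no room to place objects", "hq_generator_error")
  tries <- 0L
  while ((is.null(centers) || nrow(centers) < n) && tries < 4000L) {
    tries <- tries + 1L
    k <- idx[sample.int(length(idx), 1L)]
    r0 <- (k - 1L) %% H + 1L
    c0 <- (k - 1L) %/% H + 1L
    rad <- stats::runif(1, r_range[1L], r_range[2L])
    if (!is.null(centers)) {
      d <- sqrt((centers[, 1L] - r0)^2 + (centers[, 2L] - c0)^2)
      if (any(d < centers[, 3L] + rad + min_gap)) next
    }
    mask <- .add_disc(mask, r0, c0, rad)
    centers <- rbind(centers, c(r0, c0, rad))
  }
  if (is.null(centers) || nrow(centers) < n)
    .hq_stop("could not place requested objects without overlap", "hq_generator_error")
  list(mask = mask, centers = centers)
}

.generator_cfg <- function() hq_config()

#' Generate a synthetic H&E image with exact ground truth
#'
#' Builds a tissue blob with eosin-toned cytoplasm and scattered hematoxylin
#' nuclei, then places white near-circular fat vacuoles, dense small-nucleus
#' inflammatory foci, and large pale ballooned cells with a retained nucleus.
#' Colours come from the configured H&E stain vectors; Gaussian pixel noise is
#' added at `noise_sd`. The generator resamples (up to `cfg$synth$max_attempts`
#' times, re-seeding deterministically) until each realized fraction is within
#' `cfg$synth$rejection_tol` of its target.
#'
#' @param params a [synth_params()].
#' @param cfg configuration from [hq_config()].
#' @return object of class `synthetic_truth`: list with `image` (an H&E
#'   [rgb_image()]), `masks` (tissue, fat, inflammation, ballooning),
#'   `realized` (named fractions of tissue), `geometry` (placed objects) and
#'   `params`.
#' @export
generate_hne <- function(params, cfg = hq_config()) {
  stopifnot(inherits(params, "synth_params"))
  tol <- cfg$synth$rejection_tol
  last <- NULL
  for (attempt in seq_len(cfg$synth$max_attempts)) {
    set.seed(params$seed + (attempt - 1L) * 997L)
    out <- .gen_hne_once(params, cfg)
    dev <- abs(out$realized - c(fat = params$target_fat_frac,
                                inflammation = params$target_inflam_frac,
                                ballooning = params$target_balloon_frac))
    checked <- c(is.null(params$n_vacuoles), is.null(params$n_foci),
                 is.null(params$n_balloon_cells))
    if (all(dev[checked] <= tol)) return(out)
    last <- dev
  }
  .hq_stop(sprintf("generator missed targets after %d attempts (deviations: %s)",
                   cfg$synth$max_attempts,
                   paste(sprintf("%s=%.3f", names(last), last), collapse = ", ")),
           "hq_generator_error")
}

.gen_hne_once <- function(p, cfg) {
  H <- p$image_px[1L]; W <- p$image_px[2L]
  tissue <- .tissue_blob(H, W, p$tissue_frac)
  ta <- sum(tissue)

  # inflammatory foci first: they claim contiguous room
  foci <- matrix(FALSE, H, W)
  foci_centers <- NULL
  want_foci <- !is.null(p$n_foci) || p$target_inflam_frac > 0
  if (want_foci) {
    allowed <- .erode(tissue, ceiling(p$focus_r[2L]) + 2L)
    target <- p$target_inflam_frac * ta
    idx <- which(allowed)
    area <- 0; tries <- 0L
    while (tries < 2000L && length(idx)) {
      if (!is.null(p$n_foci)) { if (!is.null(foci_centers) && nrow(foci_centers) >= p$n_foci) break }
      else if (area >= target) break
      tries <- tries + 1L
      k <- idx[sample.int(length(idx), 1L)]
      r0 <- (k - 1L) %% H + 1L; c0 <- (k - 1L) %/% H + 1L
      rad <- stats::runif(1, p$focus_r[1L], p$focus_r[2L])
      if (is.null(p$n_foci)) {
        remaining <- target - area
        rad <- min(rad, max(sqrt(remaining / pi), 10))
      }
      if (!is.null(foci_centers)) {
        d <- sqrt((foci_centers[, 1L] - r0)^2 + (foci_centers[, 2L] - c0)^2)
        if (any(d < foci_centers[, 3L] + rad + 8)) next
      }
      foci <- .add_disc(foci, r0, c0, rad)
      foci_centers <- rbind(foci_centers, c(r0, c0, rad))
      area <- area + .disc_area(rad)
    }
  }

  # hepatocyte-scale sites for vacuoles and ballooned cells
  rmax <- max(p$fat_r[2L], p$balloon_r[2L])
  pitch <- max(28, 2 * (rmax + 2))
  interior <- .erode(tissue, ceiling(rmax) + 2L)
  if (any(foci)) {
    excl <- foci
    if (!is.null(foci_centers))
      for (i in seq_len(nrow(foci_centers)))
        excl <- .add_disc(excl, foci_centers[i, 1L], foci_centers[i, 2L],
                          foci_centers[i, 3L] + rmax + 1)
    interior <- interior & !excl
  }
  count_driven <- !is.null(p$n_vacuoles) || !is.null(p$n_balloon_cells)
  balloon <- fat <- matrix(FALSE, H, W)
  balloon_centers <- fat_centers <- NULL
  if (count_driven) {
    if (!is.null(p$n_balloon_cells) && p$n_balloon_cells > 0) {
      d <- .dart_discs(H, W, interior, p$n_balloon_cells, p$balloon_r)
      balloon <- d$mask; balloon_centers <- d$centers
      interior <- interior & !.dilate(balloon, ceiling(rmax) + 2L)
    }
    if (!is.null(p$n_vacuoles) && p$n_vacuoles > 0) {
      d <- .dart_discs(H, W, interior, p$n_vacuoles, p$fat_r)
      fat <- d$mask; fat_centers <- d$centers
    }
  } else {
    sites <- .hex_sites(H, W, interior, pitch = pitch, jitter = 1.5)
    nsite <- nrow(sites)
    b_target <- p$target_balloon_frac * ta
    f_target <- p$target_fat_frac * ta
    bfill <- .fill_sites(H, W, sites, 1L, p$balloon_r, target_area = b_target)
    balloon <- bfill$mask; balloon_centers <- bfill$centers
    # widen vacuole radii when the remaining sites could not carry the target
    fat_r <- p$fat_r
    left <- max(nsite - bfill$next_site + 1L, 1L)
    er2 <- function(r) (r[1L]^2 + r[1L] * r[2L] + r[2L]^2) / 3
    if (f_target > 0.85 * left * pi * er2(fat_r)) {
      need <- f_target / (0.85 * left * pi)
      r2 <- fat_r[2L]
      r1 <- (-r2 + sqrt(r2^2 + 4 * (3 * need - r2^2))) / 2
      fat_r[1L] <- min(max(fat_r[1L], r1), r2 - 0.3)
    }
    ffill <- .fill_sites(H, W, sites, bfill$next_site, fat_r, target_area = f_target)
    fat <- ffill$mask; fat_centers <- ffill$centers
  }

  # nuclei: scattered singles, dense packs inside foci, one per ballooned cell
  nuclei <- matrix(FALSE, H, W)
  free <- tissue & !fat & !balloon & !foci
  allowed_n <- .erode(free, 5L)
  idx <- which(allowed_n)
  n_scatter <- round(sum(free) / 900)
  if (length(idx) && n_scatter > 0) {
    pick <- idx[sample.int(length(idx), min(n_scatter, length(idx)))]
    for (k in pick)
      nuclei <- .add_disc(nuclei, (k - 1L) %% H + 1L, (k - 1L) %/% H + 1L, 2)
  }
  if (!is.null(foci_centers)) {
    for (i in seq_len(nrow(foci_centers))) {
      fc <- foci_centers[i, ]
      nf <- max(3L, round(pi * fc[3L]^2 / 80))
      ang <- stats::runif(nf, 0, 2 * pi)
      rr <- sqrt(stats::runif(nf)) * max(fc[3L] - 3, 1)
      for (j in seq_len(nf))
        nuclei <- .add_disc(nuclei, fc[1L] + rr[j] * sin(ang[j]),
                            fc[2L] + rr[j] * cos(ang[j]), 2)
    }
  }
  balloon_nuclei <- matrix(FALSE, H, W)
  if (!is.null(balloon_centers))
    for (i in seq_len(nrow(balloon_centers)))
      balloon_nuclei <- .add_disc(balloon_nuclei, balloon_centers[i, 1L],
                                  balloon_centers[i, 2L], 2.5)

  # stain-density maps
  h <- matrix(0, H, W); e <- matrix(0, H, W)
  nt <- sum(tissue)
  h[tissue] <- 0.10 + stats::rnorm(nt, 0, 0.012)
  e[tissue] <- 0.60 + stats::rnorm(nt, 0, 0.030)
  if (any(foci)) {
    nf <- sum(foci)
    h[foci] <- 0.80 + stats::rnorm(nf, 0, 0.030)
    e[foci] <- 0.55 + stats::rnorm(nf, 0, 0.030)
  }
  if (any(balloon)) {
    nb <- sum(balloon)
    h[balloon] <- 0.08 + stats::rnorm(nb, 0, 0.010)
    e[balloon] <- 0.22 + stats::rnorm(nb, 0, 0.015)
  }
  if (any(fat)) {
    h[fat] <- 0.02
    e[fat] <- 0.02
  }
  nuc_all <- nuclei | balloon_nuclei
  if (any(nuc_all)) {
    nn <- sum(nuc_all)
    h[nuc_all] <- 1.20 + stats::rnorm(nn, 0, 0.050)
    e[nuc_all] <- 0.15
  }
  h <- pmax(h, 0); e <- pmax(e, 0)

  M <- .stain_matrix(cfg)
  px <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    od <- h * M[ch, 1L] + e * M[ch, 2L]
    px[, , ch] <- 256 * 10^(-od) - 1
  }
  if (p$noise_sd > 0) px <- px + stats::rnorm(length(px), 0, p$noise_sd)
  px <- round(pmin(pmax(px, 0), 255))

  ballooning <- balloon | (balloon_nuclei & balloon)
  realized <- c(fat = sum(fat & tissue) / ta,
                inflammation = sum(foci & tissue) / ta,
                ballooning = sum(ballooning & tissue) / ta)
  geometry <- rbind(
    if (!is.null(fat_centers)) data.frame(class = "fat", row = fat_centers[, 1L],
                                          col = fat_centers[, 2L], radius = fat_centers[, 3L]),
    if (!is.null(foci_centers)) data.frame(class = "inflammation", row = foci_centers[, 1L],
                                           col = foci_centers[, 2L], radius = foci_centers[, 3L]),
    if (!is.null(balloon_centers)) data.frame(class = "ballooning", row = balloon_centers[, 1L],
                                              col = balloon_centers[, 2L], radius = balloon_centers[, 3L]))
  structure(list(
    image = rgb_image(px, stain_kind = "HE"),
    masks = list(tissue = binary_mask(tissue, "tissue"),
                 fat = binary_mask(fat, "fat"),
                 inflammation = binary_mask(foci, "inflammation"),
                 ballooning = binary_mask(ballooning, "ballooning")),
    realized = realized,
    geometry = geometry,
    params = p
  ), class = "synthetic_truth")
}

#' Generate a synthetic Sirius-red image with exact ground truth
#'
#' Yellow-toned counterstained tissue with red collagen septa laid down as
#' smooth random-walk strands; optionally a capsule arc along the tissue
#' boundary and vessel rings with white lumina, both flagged structural in the
#' truth. `target_cpa_frac` refers to the non-structural (septal) collagen
#' fraction of tissue.
#'
#' @inheritParams generate_hne
#' @return a `synthetic_truth` with masks `tissue`, `collagen`, `structural`
#'   and realized fraction `cpa` (septal collagen / tissue).
#' @export
generate_sirius_red <- function(params, cfg = hq_config()) {
  stopifnot(inherits(params, "synth_params"))
  tol <- cfg$synth$rejection_tol
  last <- NULL
  for (attempt in seq_len(cfg$synth$max_attempts)) {
    set.seed(params$seed + 499L + (attempt - 1L) * 991L)
    out <- .gen_sr_once(params, cfg)
    dev <- abs(out$realized[["cpa"]] - params$target_cpa_frac)
    if (!is.null(params$n_septa) || dev <= tol) return(out)
    last <- dev
  }
  .hq_stop(sprintf("generator missed CPA target after %d attempts (deviation %.3f)",
                   cfg$synth$max_attempts, last), "hq_generator_error")
}

.gen_sr_once <- function(p, cfg) {
  H <- p$image_px[1L]; W <- p$image_px[2L]
  tissue <- .tissue_blob(H, W, p$tissue_frac)
  ta <- sum(tissue)
  interior <- .erode(tissue, 28L)

  septa <- matrix(FALSE, H, W)
  keepout <- matrix(FALSE, H, W)
  target <- p$target_cpa_frac * ta
  n_strands <- 0L
  want <- if (!is.null(p$n_septa)) p$n_septa else Inf
  tries <- 0L
  idx <- which(interior)
  area_done <- 0L
  while (tries < 2000L && length(idx)) {
    if (!is.null(p$n_septa)) { if (n_strands >= want) break }
    else if (area_done >= target) break
    tries <- tries + 1L
    k <- idx[sample.int(length(idx), 1L)]
    r0 <- (k - 1L) %% H + 1L; c0 <- (k - 1L) %/% H + 1L
    # strands thin out when placement gets crowded
    wd <- stats::runif(1, 2, if (tries > 400L) 2.2 else 3.5)
    nstep <- round(stats::runif(1, 40, 120))
    if (is.null(p$n_septa)) {
      remaining <- max(target - area_done, 0)
      nstep <- min(nstep, max(20L, round(remaining / (2 * (2 * wd)))))
    }
    heading <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(nstep, 0, 0.12))
    rr <- r0 + cumsum(2 * sin(heading))
    cc <- c0 + cumsum(2 * cos(heading))
    ir <- pmin(pmax(round(rr), 1L), H)
    ic <- pmin(pmax(round(cc), 1L), W)
    inside <- interior[cbind(ir, ic)]
    stop_at <- if (all(inside)) nstep else which(!inside)[1L] - 1L
    if (stop_at < 20L) next
    # cheap pre-check on the centreline before the expensive dilation
    if (any(keepout[cbind(ir[1:stop_at], ic[1:stop_at])])) next
    path <- matrix(FALSE, H, W)
    path[cbind(ir[1:stop_at], ic[1:stop_at])] <- TRUE
    strand <- .dilate(path, ceiling(wd))
    if (any(strand & keepout)) next
    septa <- septa | strand
    area_done <- area_done + sum(strand)
    # a 1-px gap keeps strands as separate 4-connected components
    keepout <- keepout | .dilate(strand, 1L)
    n_strands <- n_strands + 1L
  }

  capsule <- matrix(FALSE, H, W)
  if (isTRUE(p$include_capsule)) {
    band <- tissue & !.erode(tissue, 8L)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    th0 <- stats::runif(1, 0, 2 * pi)
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    ang <- (atan2(rows - cy, cols - cx) - th0) %% (2 * pi)
    capsule <- band & ang <= 2 * pi / 3
  }
  vessels <- matrix(FALSE, H, W)
  lumen <- matrix(FALSE, H, W)
  if (isTRUE(p$include_vessels)) {
    vint <- .erode(tissue, 30L)
    vidx <- which(vint)
    placed <- 0L; vtries <- 0L
    while (placed < 2L && vtries < 200L && length(vidx)) {
      vtries <- vtries + 1L
      k <- vidx[sample.int(length(vidx), 1L)]
      r0 <- (k - 1L) %% H + 1L; c0 <- (k - 1L) %/% H + 1L
      outer_r <- stats::runif(1, 16, 20)
      ring <- .add_disc(matrix(FALSE, H, W), r0, c0, outer_r)
      if (any(ring & (keepout | .dilate(vessels, 3L) | capsule))) next
      inner <- .add_disc(matrix(FALSE, H, W), r0, c0, outer_r - 5)
      vessels <- vessels | (ring & !inner)
      lumen <- lumen | inner
      placed <- placed + 1L
    }
  }

  collagen <- septa | capsule | vessels
  structural <- capsule | vessels

  R <- matrix(252, H, W); G <- matrix(252, H, W); B <- matrix(252, H, W)
  nt <- sum(tissue)
  R[tissue] <- 235 + stats::rnorm(nt, 0, 2)
  G[tissue] <- 220 + stats::rnorm(nt, 0, 2)
  B[tissue] <- 170 + stats::rnorm(nt, 0, 3)
  nc <- sum(collagen)
  if (nc) {
    R[collagen] <- 185 + stats::rnorm(nc, 0, 4)
    G[collagen] <- 45 + stats::rnorm(nc, 0, 4)
    B[collagen] <- 55 + stats::rnorm(nc, 0, 4)
  }
  if (any(lumen)) { R[lumen] <- 250; G[lumen] <- 250; B[lumen] <- 250 }
  px <- array(c(R, G, B), c(H, W, 3L))
  if (p$noise_sd > 0) px <- px + stats::rnorm(length(px), 0, p$noise_sd)
  px <- round(pmin(pmax(px, 0), 255))

  structure(list(
    image = rgb_image(px, stain_kind = "SIRIUS_RED"),
    masks = list(tissue = binary_mask(tissue, "tissue"),
                 collagen = binary_mask(collagen, "collagen"),
                 structural = binary_mask(structural, "structural")),
    realized = c(cpa = sum(septa & tissue) / ta),
    geometry = NULL,
    params = p
  ), class = "synthetic_truth")
}

#' Per-pixel ground-truth label mask of a synthetic H&E image
#'
#' @param truth a `synthetic_truth` from [generate_hne()].
#' @return an integer `label_mask` with classes background, tissue_other, fat,
#'   inflammation, ballooning.
#' @export
label_mask_from_truth <- function(truth) {
  m <- truth$masks
  classes <- c("background", "tissue_other", "fat", "inflammation", "ballooning")
  out <- matrix(1L, nrow(m$tissue), ncol(m$tissue))
  out[m$tissue] <- 2L
  out[m$fat] <- 3L
  out[m$inflammation] <- 4L
  out[m$ballooning] <- 5L
  structure(out, classes = classes, class = c("label_mask", "matrix", "array"))
}

#' GeoJSON-style annotations derived from synthetic ground truth
#'
#' Emits one polygon per placed object (circles as 28-gons), mimicking
#' pathologist annotations for classifier-training tests.
#'
#' @param truth a `synthetic_truth` from [generate_hne()].
#' @return an [annotation_set()].
#' @export
synth_annotations <- function(truth) {
  g <- truth$geometry
  if (is.null(g) || nrow(g) == 0L) return(annotation_set())
  regions <- lapply(seq_len(nrow(g)), function(i) {
    th <- seq(0, 2 * pi, length.out = 29L)[-29L]
    rad <- g$radius[i] + 0.25
    list(xy = cbind(x = g$col[i] - 0.5 + rad * cos(th),
                    y = g$row[i] - 0.5 + rad * sin(th)),
         class = g$class[i], annotator = "synthetic-truth")
  })
  annotation_set(regions)
}

#' Generate a synthetic cohort mirroring a mild/moderate/severe case mix
#'
#' Per-case targets are drawn lognormally (log-sd 0.2) around stratum medians
#' taken from published derivation-cohort values (fat 2.6/15.1/28.4%,
#' inflammation 0.9/1.1/3.8%, ballooning 4.9/17.8/23%, CPA 1.3/2.4/13%), and a
#' pseudo NASH CRN score is assigned from the generating stratum. Everything is
#' seeded and deterministic.
#'
#' @param n_cases number of cases.
#' @param grade_mix length-3 vector of stratum proportions (must sum to 1).
#' @param seed integer seed.
#' @param image_px image size `c(H, W)`.
#' @param include_sr also generate the paired Sirius-red image.
#' @param cfg configuration from [hq_config()].
#' @return list of cases; each has `case_id`, `stratum`, `crn` (one-row
#'   data.frame), `hne` and (optionally) `sr` `synthetic_truth` objects.
#' @export
generate_cohort <- function(n_cases, grade_mix = rep(1 / 3, 3), seed,
                            image_px = c(768L, 768L), include_sr = TRUE,
                            cfg = hq_config()) {
  if (abs(sum(grade_mix) - 1) > 1e-8 || length(grade_mix) != 3L || any(grade_mix < 0))
    .hq_stop("grade_mix must be 3 nonnegative proportions summing to 1", "hq_param_error")
  counts <- diff(c(0L, round(cumsum(grade_mix) * n_cases)))
  strata <- rep(1:3, counts)
  med <- list(fat = c(0.026, 0.151, 0.284),
              inflam = c(0.009, 0.011, 0.038),
              balloon = c(0.049, 0.178, 0.230),
              cpa = c(0.013, 0.024, 0.130))
  crn_tab <- data.frame(steatosis_grade = 1:3,
                        lobular_inflammation = c(0L, 1L, 2L),
                        ballooning = c(0L, 1L, 2L),
                        fibrosis_stage = c("0", "2", "4"))
  set.seed(seed)
  case_seeds <- sample.int(2147480000L, n_cases)
  mult <- matrix(exp(stats::rnorm(4L * n_cases, 0, 0.2)), n_cases, 4L)
  lapply(seq_len(n_cases), function(i) {
    s <- strata[i]
    tf <- min(med$fat[s] * mult[i, 1L], 0.40)
    ti <- min(med$inflam[s] * mult[i, 2L], 0.07)
    tb <- min(med$balloon[s] * mult[i, 3L], 0.28)
    tc <- min(med$cpa[s] * mult[i, 4L], 0.18)
    tot <- tf + ti + tb
    if (tot > 0.52) { sc <- 0.52 / tot; tf <- tf * sc; ti <- ti * sc; tb <- tb * sc }
    ph <- synth_params(image_px = image_px, target_fat_frac = tf,
                       target_inflam_frac = ti, target_balloon_frac = tb,
                       target_cpa_frac = tc,
                       include_capsule = s == 3L, include_vessels = s >= 2L,
                       seed = case_seeds[i])
    crn <- crn_tab[s, , drop = FALSE]
    crn$nas <- crn$steatosis_grade + crn$lobular_inflammation + crn$ballooning
    list(case_id = sprintf("case%03d", i), stratum = s, crn = crn,
         hne = generate_hne(ph, cfg),
         sr = if (include_sr) generate_sirius_red(ph, cfg) else NULL)
  })
}
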