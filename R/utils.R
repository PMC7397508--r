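# Internal helpers shared across modules. All raster code uses 1-based
# (row, col) matrix indexing internally; user-facing polygon coordinates are
# 0-based (x = col, y = row) with half-open pixel coverage.

.hq_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "hepaquant_error", "error", "condition")))
}

#' @importFrom EBImage bwlabel
.label_mask <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

.component_areas <- function(lab) {
  if (max(lab) == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = max(lab))
}

# keep only components whose id is in `keep`
.filter_components <- function(lab, keep) {
  out <- lab > 0L & lab %in% keep
  matrix(out, nrow(lab), ncol(lab))
}

.disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

.erode <- function(mask, radius) {
  if (radius < 1) return(mask)
  m <- EBImage::erode(matrix(as.numeric(mask), nrow(mask), ncol(mask)), .disc_brush(radius))
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

.dilate <- function(mask, radius) {
  if (radius < 1) return(mask)
  m <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)), .disc_brush(radius))
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

.close_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  .erode(.dilate(mask, radius), radius)
}

# Box-filter sum over a (2r+1)^2 window clamped at image borders, via summed
# area table. Returns a matrix of the same size.
.box_sum <- function(m, window) {
  r <- (as.integer(window) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 1L, W + 1L)
  P[-1L, -1L] <- apply(m, 2L, cumsum)
  P[-1L, -1L] <- t(apply(P[-1L, -1L, drop = FALSE], 1L, cumsum))
  r1 <- pmax(seq_len(H) - r, 1L); r2 <- pmin(seq_len(H) + r, H)
  c1 <- pmax(seq_len(W) - r, 1L); c2 <- pmin(seq_len(W) + r, W)
  P[r2 + 1L, c2 + 1L, drop = FALSE] - P[r1, c2 + 1L, drop = FALSE] -
    P[r2 + 1L, c1, drop = FALSE] + P[r1, c1, drop = FALSE]
}

.box_count <- function(H, W, window) {
  r <- (as.integer(window) - 1L) %/% 2L
  nr <- pmin(seq_len(H) + r, H) - pmax(seq_len(H) - r, 1L) + 1L
  nc <- pmin(seq_len(W) + r, W) - pmax(seq_len(W) - r, 1L) + 1L
  outer(nr, nc)
}

.box_mean <- function(m, window) .box_sum(m, window) / .box_count(nrow(m), ncol(m), window)

.box_sd <- function(m, window) {
  mu <- .box_mean(m, window)
  v <- .box_mean(m * m, window) - mu * mu
  sqrt(pmax(v, 0))
}

# Local maxima of a grayscale map: pixels equal to the max of their
# (2r+1)^2 neighbourhood and at least `floor` high.
.local_maxima <- function(m, radius = 2L, floor = 0) {
  mx <- EBImage::dilate(m, EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "box"))
  m >= mx & m >= floor
}

# Otsu threshold on a numeric vector (maximises between-class variance).
.otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(pmax(findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1L),
                                       rightmost.closed = TRUE), 1L), n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (mids[-1L] + mids[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# Saturation in [0,1] of an H x W x 3 array on the 0..255 scale.
.rgb_saturation <- function(px) {
  mx <- pmax(px[, , 1L], px[, , 2L], px[, , 3L])
  mn <- pmin(px[, , 1L], px[, , 2L], px[, , 3L])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

.rgb_min <- function(px) pmin(px[, , 1L], px[, , 2L], px[, , 3L])

# Deterministic polynomial hash of any R object (config fingerprinting).
.hq_hash <- function(x) {
  b <- as.integer(serialize(x, connection = NULL, ascii = TRUE))
  h <- 0
  for (i in seq(1L, length(b), by = 64L)) {
    chunk <- b[i:min(i + 63L, length(b))]
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

.mask_area <- function(mask) sum(mask)

.same_shape <- function(a, b) identical(dim(a)[1:2], dim(b)[1:2])

# Paint a rasterized disk into a logical matrix; returns modified matrix.
# Pixel (i, j) belongs to the disk iff (i - r0)^2 + (j - c0)^2 <= rad^2.
.add_disc <- function(mask, r0, c0, rad) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
  ci <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
  sub <- outer((ri - r0)^2, (ci - c0)^2, "+") <= rad^2
  mask[ri, ci] <- mask[ri, ci] | sub
  mask
}

.disc_area <- function(rad) {
  ri <- (-ceiling(rad)):ceiling(rad)
  sum(outer(ri^2, ri^2, "+") <= rad^2)
}
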