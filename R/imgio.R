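# Image and annotation I/O, plus the tissue mask that is the denominator of
# every reported percentage.

#' Construct an RGB image object
#'
#' @param pixels H x W x 3 numeric array of 8-bit intensities (0-255).
#' @param stain_kind one of `"HE"`, `"SIRIUS_RED"`, `"UNKNOWN"`.
#' @param pixel_size_um optional physical pixel size in micrometres per pixel.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, stain_kind = c("UNKNOWN", "HE", "SIRIUS_RED"),
                      pixel_size_um = NULL) {
  stain_kind <- match.arg(stain_kind)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    .hq_stop(sprintf("expected an H x W x 3 array, got %s channel(s)",
                     if (length(dim(pixels)) == 3L) dim(pixels)[3L] else 1L),
             "hq_format_error")
  if (dim(pixels)[1L] < 64L || dim(pixels)[2L] < 64L)
    .hq_stop("image must be at least 64 x 64 pixels", "hq_format_error")
  if (min(pixels) < 0 || max(pixels) > 255)
    .hq_stop("intensities must lie in [0, 255]", "hq_format_error")
  if (!is.null(pixel_size_um) && (!is.numeric(pixel_size_um) || pixel_size_um <= 0))
    .hq_stop("pixel_size_um must be a positive number", "hq_format_error")
  structure(list(pixels = pixels, stain_kind = stain_kind,
                 pixel_size_um = pixel_size_um),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %d x %d, stain %s%s>\n", d[1], d[2], x$stain_kind,
              if (is.null(x$pixel_size_um)) "" else
                sprintf(", %.3g um/px", x$pixel_size_um)))
  invisible(x)
}

#' Construct a binary mask aligned to an image
#'
#' @param pixels logical H x W matrix.
#' @param label feature name carried by the mask.
#' @return logical matrix of class `binary_mask` with a `label` attribute.
#' @export
binary_mask <- function(pixels, label = "mask") {
  if (!is.matrix(pixels)) .hq_stop("mask must be a matrix", "hq_format_error")
  storage.mode(pixels) <- "logical"
  structure(pixels, label = label, class = c("binary_mask", "matrix", "array"))
}

#' Read a TIFF or PNG photomicrograph
#'
#' Grayscale (single-channel) files are rejected: stain-based segmentation
#' needs colour. A fourth (alpha) channel, if present, is dropped.
#'
#' @param path path to an 8-bit RGB TIFF or PNG file.
#' @param stain_kind stain of the slide (`"HE"`, `"SIRIUS_RED"`, `"UNKNOWN"`).
#' @param pixel_size_um optional micrometres per pixel.
#' @return an [rgb_image()].
#' @export
load_image <- function(path, stain_kind = c("UNKNOWN", "HE", "SIRIUS_RED"),
                       pixel_size_um = NULL) {
  stain_kind <- match.arg(stain_kind)
  if (!file.exists(path)) .hq_stop(sprintf("file not found: %s", path), "hq_io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = , tiff = tiff::readTIFF(path),
           .hq_stop(sprintf("unsupported image format '.%s'", ext), "hq_io_error")),
    error = function(e) .hq_stop(sprintf("cannot read %s: %s", path, conditionMessage(e)),
                                 "hq_io_error"))
  if (is.matrix(raw) || dim(raw)[3L] == 1L)
    .hq_stop("grayscale image (1 channel); an RGB image is required", "hq_format_error")
  if (dim(raw)[3L] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3L] != 3L)
    .hq_stop(sprintf("expected 3 colour channels, got %d", dim(raw)[3L]), "hq_format_error")
  rgb_image(round(raw * 255), stain_kind = stain_kind, pixel_size_um = pixel_size_um)
}

#' Write an RGB image to PNG or TIFF
#'
#' @param image an [rgb_image()].
#' @param path destination path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(arr, path),
         tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
         .hq_stop(sprintf("unsupported image format '.%s'", ext), "hq_io_error"))
  invisible(path)
}

#' Export a binary mask as a single-channel PNG (0/255)
#' @param mask a [binary_mask()].
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 single-channel PNG back into a binary mask
#' @param path PNG path.
#' @param label feature name for the mask.
#' @return a [binary_mask()].
#' @export
read_mask_png <- function(path, label = "mask") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  binary_mask(m > 0.5, label = label)
}

#' Compute the tissue mask of a slide image
#'
#' Background is defined as bright, low-saturation pixels (near-white slide
#' glass in both stains). Connected tissue fragments smaller than
#' `min_component_px` are dropped as debris; interior holes up to
#' `max_hole_px` - which include fat vacuoles - are filled so that vacuoles
#' count in the tissue denominator. When the image carries a physical pixel
#' size, `min_component_px` is rescaled by `pixel_size_um^-2` (the default is
#' expressed at 1 um/px).
#'
#' @param image an [rgb_image()].
#' @param min_component_px minimum tissue fragment area in pixels; defaults to
#'   the config value.
#' @param cfg configuration from [hq_config()].
#' @return a [binary_mask()] labelled `"tissue"`.
#' @export
compute_tissue_mask <- function(image, min_component_px = NULL, cfg = hq_config()) {
  stopifnot(inherits(image, "rgb_image"))
  tc <- cfg$tissue
  if (is.null(min_component_px)) min_component_px <- tc$min_component_px
  if (!is.null(image$pixel_size_um))
    min_component_px <- round(min_component_px * image$pixel_size_um^-2)
  px <- image$pixels
  bg <- .rgb_min(px) >= tc$bg_min_rgb & .rgb_saturation(px) < tc$bg_max_sat
  tissue <- !bg
  # drop small debris
  lab <- .label_mask(tissue)
  areas <- .component_areas(lab)
  keep <- which(areas >= min_component_px)
  if (length(keep) == 0L)
    .hq_stop("no tissue found in image", "hq_no_tissue_error")
  tissue <- .filter_components(lab, keep)
  # fill interior holes (not touching the border) up to max_hole_px
  holes <- !tissue
  hlab <- .label_mask(holes)
  border_ids <- unique(c(hlab[1L, ], hlab[nrow(hlab), ], hlab[, 1L], hlab[, ncol(hlab)]))
  hareas <- .component_areas(hlab)
  fill <- setdiff(which(hareas <= tc$max_hole_px), border_ids)
  if (length(fill)) tissue <- tissue | .filter_components(hlab, fill)
  binary_mask(tissue, label = "tissue")
}

# ---- annotations -----------------------------------------------------------

.HQ_CLASSES <- c("background", "tissue_other", "fat", "inflammation",
                 "ballooning", "collagen")

#' Construct an annotation set
#'
#' @param regions list of regions; each is a list with `xy` (n x 2 matrix of
#'   polygon vertices, columns x = column and y = row, 0-based pixel
#'   coordinates), `class` (one of the fixed vocabulary) and optional
#'   `annotator`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(regions = list()) {
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (is.null(r$xy) || !is.matrix(r$xy) || ncol(r$xy) != 2L || nrow(r$xy) < 3L)
      .hq_stop(sprintf("region %d: polygon needs an n x 2 vertex matrix with n >= 3", i),
               "hq_annotation_error")
    if (is.null(r$class) || !r$class %in% .HQ_CLASSES)
      .hq_stop(sprintf("region %d: class must be one of %s", i,
                       paste(.HQ_CLASSES, collapse = ", ")), "hq_annotation_error")
    if (is.null(r$annotator)) regions[[i]]$annotator <- NA_character_
  }
  structure(list(regions = regions), class = "annotation_set")
}

#' Read pathologist annotations from a GeoJSON FeatureCollection
#'
#' Expects Polygon features with the class name in `properties$label` and an
#' optional `properties$annotator`.
#'
#' @param path GeoJSON file path.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) .hq_stop(sprintf("file not found: %s", path), "hq_io_error")
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  regions <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon"))
      .hq_stop(sprintf("feature %d: only Polygon geometries are supported", i),
               "hq_annotation_error")
    ring <- f$geometry$coordinates[[1L]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    # drop the GeoJSON closing vertex
    if (nrow(xy) > 1L && all(xy[1L, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    list(xy = xy, class = f$properties$label,
         annotator = f$properties$annotator %||% NA_character_)
  })
  annotation_set(regions)
}

#' Write an annotation set to GeoJSON
#' @param ann an [annotation_set()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  feats <- lapply(ann$regions, function(r) {
    ring <- lapply(seq_len(nrow(r$xy)), function(i) c(r$xy[i, 1L], r$xy[i, 2L]))
    ring <- c(ring, ring[1L])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(label = r$class, annotator = r$annotator))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized even-odd point-in-polygon (pnpoly). Points on the 0-based pixel
# grid; polygon vertices as x (col), y (row).
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py[crosses] - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

#' Rasterize annotations into a per-pixel label mask
#'
#' Pixels are covered by a polygon iff their centre lies inside it (half-open
#' convention: the square polygon with corners (10,10)-(20,20) covers exactly
#' the 100 pixels with indices 10..19). Overlaps are resolved last-drawn-wins;
#' unannotated pixels are labelled `background`.
#'
#' @param ann an [annotation_set()].
#' @param shape integer vector `c(H, W)`.
#' @return an integer H x W matrix of class `label_mask`; attribute `classes`
#'   maps code `k` to `attr(x, "classes")[k]`, code 1 is always `background`.
#' @export
rasterize_annotations <- function(ann, shape) {
  stopifnot(inherits(ann, "annotation_set"), length(shape) == 2L)
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  classes <- union("background", vapply(ann$regions, `[[`, "", "class"))
  out <- matrix(1L, H, W)
  for (i in seq_along(ann$regions)) {
    r <- ann$regions[[i]]
    if (any(r$xy[, 1L] < 0 | r$xy[, 1L] > W | r$xy[, 2L] < 0 | r$xy[, 2L] > H))
      .hq_stop(sprintf("region %d: vertex outside [0,%d) x [0,%d)", i, W, H),
               "hq_annotation_error")
    code <- match(r$class, classes)
    rows <- max(1L, floor(min(r$xy[, 2L]))):min(H, ceiling(max(r$xy[, 2L])))
    cols <- max(1L, floor(min(r$xy[, 1L]))):min(W, ceiling(max(r$xy[, 1L])))
    grid <- expand.grid(row = rows, col = cols)
    hit <- .points_in_polygon(grid$col - 0.5, grid$row - 0.5, r$xy[, 1L], r$xy[, 2L])
    if (any(hit)) out[cbind(grid$row[hit], grid$col[hit])] <- code
  }
  structure(out, classes = classes, class = c("label_mask", "matrix", "array"))
}

#' Vectorize a binary mask into polygons
#'
#' Components that exactly fill their bounding box become rectangles (so
#' rasterize -> vectorize -> rasterize is the identity for axis-aligned
#' rectangles); other components are traced with a marching-squares contour at
#' the pixel boundary level.
#'
#' @param mask a logical matrix.
#' @param class class label for the emitted regions.
#' @return an [annotation_set()].
#' @export
polygons_from_mask <- function(mask, class = "tissue_other") {
  lab <- .label_mask(mask)
  regions <- list()
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    r1 <- min(idx[, 1L]); r2 <- max(idx[, 1L])
    c1 <- min(idx[, 2L]); c2 <- max(idx[, 2L])
    if (nrow(idx) == (r2 - r1 + 1L) * (c2 - c1 + 1L)) {
      xy <- cbind(x = c(c1 - 1L, c2, c2, c1 - 1L), y = c(r1 - 1L, r1 - 1L, r2, r2))
    } else {
      comp <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
      comp[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (lab == id) * 1
      cl <- grDevices::contourLines(x = seq_len(nrow(comp)) - 1.5,
                                    y = seq_len(ncol(comp)) - 1.5,
                                    z = comp, levels = 0.5)
      if (length(cl) == 0L) next
      lens <- vapply(cl, function(l) length(l$x), 0L)
      ring <- cl[[which.max(lens)]]
      xy <- cbind(x = ring$y, y = ring$x)  # contourLines x follows rows
    }
    regions[[length(regions) + 1L]] <- list(xy = xy, class = class)
  }
  annotation_set(regions)
}
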