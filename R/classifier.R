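# Supervised region classifier: tile features -> tree ensemble -> per-class
# probability maps. Feature extraction is versioned so alternative feature
# sets can be benchmarked without silently mixing models and extractors.

.HQ_FEATURE_NAMES <- c("r_mean", "g_mean", "b_mean", "r_sd", "g_sd", "b_sd",
                       "h_mean", "e_mean", "h_sd", "e_sd",
                       "bright_frac", "entropy", "maxima_cnt",
                       "h_mean_lg", "maxima_cnt_lg")

# Per-pixel feature maps: window statistics centred at each pixel. Training
# samples these maps at tile centres; prediction uses every pixel, so train
# and inference features come from the same definitions.
.feature_maps <- function(image, window, cfg) {
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  w <- as.integer(window); if (w %% 2L == 0L) w <- w + 1L
  sm <- unmix_hne(image, cfg)
  gray <- (px[, , 1L] + px[, , 2L] + px[, , 3L]) / 3
  bright <- .bright_mask(px, cfg$fat$brightness_thresh, cfg$fat$max_sat)
  maxima <- .local_maxima(sm$hematoxylin, radius = cfg$inflammation$maxima_radius,
                          floor = cfg$inflammation$maxima_floor)
  # windowed Shannon entropy of a 16-bin gray histogram
  cnt <- .box_count(H, W, w)
  ent <- matrix(0, H, W)
  bins <- pmin(floor(gray / 16) + 1L, 16L)
  for (b in 1:16) {
    pb <- .box_sum(matrix(as.numeric(bins == b), H, W), w) / cnt
    ok <- pb > 0
    ent[ok] <- ent[ok] - pb[ok] * log2(pb[ok])
  }
  lw <- as.integer(cfg$classifier$large_window); if (lw %% 2L == 0L) lw <- lw + 1L
  maps <- list(
    r_mean = .box_mean(px[, , 1L], w), g_mean = .box_mean(px[, , 2L], w),
    b_mean = .box_mean(px[, , 3L], w),
    r_sd = .box_sd(px[, , 1L], w), g_sd = .box_sd(px[, , 2L], w),
    b_sd = .box_sd(px[, , 3L], w),
    h_mean = .box_mean(sm$hematoxylin, w), e_mean = .box_mean(sm$eosin, w),
    h_sd = .box_sd(sm$hematoxylin, w), e_sd = .box_sd(sm$eosin, w),
    bright_frac = .box_mean(matrix(as.numeric(bright), H, W), w),
    entropy = ent,
    maxima_cnt = .box_sum(matrix(as.numeric(maxima), H, W), w),
    h_mean_lg = .box_mean(sm$hematoxylin, lw),
    maxima_cnt_lg = .box_sum(matrix(as.numeric(maxima), H, W), lw)
  )
  maps[.HQ_FEATURE_NAMES]
}

#' Extract per-tile features from an H&E image
#'
#' The image is divided into a grid of `tile_px` x `tile_px` tiles; each tile
#' yields one feature row: mean/sd of R, G, B, mean/sd of hematoxylin and eosin
#' optical density, fraction of bright low-saturation pixels, mean local
#' entropy, nuclear-maxima count, plus two larger-window context features
#' (hematoxylin mean and maxima count). Feature ordering is fixed and the table
#' carries the extractor version.
#'
#' @param image an H&E [rgb_image()].
#' @param tile_px tile edge in pixels (>= 8); defaults to
#'   `cfg$classifier$tile_px`.
#' @param cfg configuration from [hq_config()].
#' @return data.frame with one row per tile: `tile_row`, `tile_col`,
#'   `center_r`, `center_c` and the feature columns; attribute
#'   `feature_version`.
#' @export
extract_features <- function(image, tile_px = NULL, cfg = hq_config()) {
  stopifnot(inherits(image, "rgb_image"))
  if (is.null(tile_px)) tile_px <- cfg$classifier$tile_px
  if (tile_px < 8L) .hq_stop("tile_px must be at least 8", "hq_param_error")
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  nr <- H %/% tile_px; nc <- W %/% tile_px
  if (nr == 0L || nc == 0L) .hq_stop("tile grid is empty", "hq_param_error")
  maps <- .feature_maps(image, tile_px, cfg)
  cr <- (seq_len(nr) - 1L) * tile_px + ceiling(tile_px / 2)
  cc <- (seq_len(nc) - 1L) * tile_px + ceiling(tile_px / 2)
  grid <- expand.grid(center_r = cr, center_c = cc)
  out <- data.frame(tile_row = (grid$center_r - 1L) %/% tile_px + 1L,
                    tile_col = (grid$center_c - 1L) %/% tile_px + 1L,
                    center_r = grid$center_r, center_c = grid$center_c)
  idx <- cbind(grid$center_r, grid$center_c)
  for (f in .HQ_FEATURE_NAMES) out[[f]] <- maps[[f]][idx]
  attr(out, "feature_version") <- cfg$classifier$feature_version
  attr(out, "tile_px") <- tile_px
  out
}

#' Tile labels from a per-pixel label mask
#'
#' Each tile takes the majority ground-truth class when its purity is at least
#' `min_purity`; impure tiles get `NA` and are dropped from training.
#'
#' @param label_mask a `label_mask` (e.g. from [rasterize_annotations()] or
#'   [label_mask_from_truth()]).
#' @param tile_px tile edge in pixels.
#' @param min_purity minimum majority fraction.
#' @return character vector aligned with the rows of [extract_features()].
#' @export
tile_labels <- function(label_mask, tile_px, min_purity = 0.6) {
  classes <- attr(label_mask, "classes")
  H <- nrow(label_mask); W <- ncol(label_mask)
  nr <- H %/% tile_px; nc <- W %/% tile_px
  lab <- character(nr * nc)
  k <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      k <- k + 1L
      tl <- label_mask[((i - 1L) * tile_px + 1L):(i * tile_px),
                       ((j - 1L) * tile_px + 1L):(j * tile_px)]
      tb <- tabulate(tl, nbins = length(classes))
      m <- which.max(tb)
      lab[k] <- if (tb[m] / sum(tb) >= min_purity) classes[m] else NA_character_
    }
  }
  lab
}

#' Train the region classifier
#'
#' Fits a seeded random-forest (ranger) on tile features pooled across images,
#' with per-pixel labels supplied as `label_mask`s. A stratified 80/20 split
#' provides held-out accuracy and per-class recall, stored in `training_meta`.
#'
#' @param images list of H&E [rgb_image()]s.
#' @param label_masks list of aligned `label_mask`s.
#' @param seed integer seed (training is bit-reproducible for a fixed seed).
#' @param cfg configuration from [hq_config()]; classifier hyperparameters
#'   under `cfg$classifier` (`n_trees`, `max_depth`, `tile_px`, ...).
#' @return object of class `region_model`.
#' @export
train_region_model <- function(images, label_masks, seed, cfg = hq_config()) {
  stopifnot(length(images) == length(label_masks), length(images) >= 1L)
  cc <- cfg$classifier
  feats <- list(); labs <- list()
  for (i in seq_along(images)) {
    ft <- extract_features(images[[i]], cc$tile_px, cfg)
    lb <- tile_labels(label_masks[[i]], cc$tile_px, cc$min_purity)
    feats[[i]] <- ft; labs[[i]] <- lb
  }
  X <- do.call(rbind, feats)[, .HQ_FEATURE_NAMES]
  y <- unlist(labs)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  tab <- table(y)
  if (length(tab) < 2L)
    .hq_stop("need at least 2 annotated classes", "hq_training_error")
  low <- names(tab)[tab < cc$min_tiles_per_class]
  if (length(low))
    .hq_stop(sprintf("class '%s' has fewer than %d labelled tiles (%d)",
                     low[1L], cc$min_tiles_per_class, tab[low[1L]]),
             "hq_training_error")
  y <- factor(y)
  set.seed(seed)
  holdout <- unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(0.2 * length(idx))))
  }))
  train_idx <- setdiff(seq_along(y), holdout)
  fit <- ranger::ranger(x = X[train_idx, , drop = FALSE], y = y[train_idx],
                        num.trees = cc$n_trees, max.depth = cc$max_depth,
                        probability = TRUE, seed = seed, num.threads = 1L)
  ph <- predict(fit, X[holdout, , drop = FALSE], num.threads = 1L)$predictions
  pred <- colnames(ph)[max.col(ph, ties.method = "first")]
  truth <- as.character(y[holdout])
  recall <- vapply(levels(y), function(cl) {
    n <- sum(truth == cl); if (n == 0) NA_real_ else mean(pred[truth == cl] == cl)
  }, 0)
  structure(list(
    fit = fit,
    feature_names = .HQ_FEATURE_NAMES,
    classes = levels(y),
    feature_version = cc$feature_version,
    tile_px = cc$tile_px,
    training_meta = list(n_images = length(images),
                         n_tiles = as.list(tab), seed = seed,
                         holdout_accuracy = mean(pred == truth),
                         per_class_recall = as.list(recall),
                         version = cfg$method_version)
  ), class = "region_model")
}

#' Per-class probability maps for an image
#'
#' Evaluates the trained ensemble at every pixel using sliding-window features
#' (same definitions as training tiles), giving per-class probability maps at
#' pixel resolution; probabilities sum to 1 at each pixel.
#'
#' @param model a [region_model][train_region_model()].
#' @param image an H&E [rgb_image()].
#' @param cfg configuration from [hq_config()].
#' @return list with `prob` (H x W x n_classes array) and `classes`.
#' @export
predict_map <- function(model, image, cfg = hq_config()) {
  stopifnot(inherits(model, "region_model"), inherits(image, "rgb_image"))
  if (!identical(model$feature_version, cfg$classifier$feature_version))
    .hq_stop(sprintf("feature version mismatch: model %s vs extractor %s",
                     model$feature_version, cfg$classifier$feature_version),
             "hq_compat_error")
  maps <- .feature_maps(image, model$tile_px, cfg)
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  X <- do.call(cbind, lapply(maps, as.vector))
  colnames(X) <- .HQ_FEATURE_NAMES
  K <- length(model$classes)
  prob <- matrix(0, H * W, K)
  colnames(prob) <- model$classes
  chunk <- 250000L
  for (s in seq(1L, nrow(X), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(X))
    pr <- predict(model$fit, data.frame(X[s:e, , drop = FALSE]), num.threads = 1L)$predictions
    prob[s:e, colnames(pr)] <- pr
  }
  list(prob = array(prob, c(H, W, K)), classes = model$classes)
}

.class_prob <- function(pm, class) {
  k <- match(class, pm$classes)
  if (is.na(k)) return(matrix(0, dim(pm$prob)[1L], dim(pm$prob)[2L]))
  pm$prob[, , k]
}

#' Hard class assignment from probability maps
#' @param pm output of [predict_map()].
#' @return a `label_mask` of argmax classes.
#' @export
classify_map <- function(pm) {
  d <- dim(pm$prob)
  flat <- matrix(pm$prob, d[1L] * d[2L], d[3L])
  structure(matrix(max.col(flat, ties.method = "first"), d[1L], d[2L]),
            classes = pm$classes, class = c("label_mask", "matrix", "array"))
}
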