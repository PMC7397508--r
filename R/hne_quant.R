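# H&E quantitation: fat vacuoles, inflammatory infiltrate, ballooned
# hepatocytes, each expressed as a percentage of tissue area.

.check_hne_inputs <- function(image, tissue) {
  stopifnot(inherits(image, "rgb_image"))
  if (image$stain_kind != "HE")
    .hq_stop(sprintf("expected an HE image, got stain_kind = %s", image$stain_kind),
             "hq_stain_error")
  if (!.same_shape(image$pixels, tissue))
    .hq_stop("tissue mask shape does not match image", "hq_format_error")
  if (.mask_area(tissue) == 0L)
    .hq_stop("tissue mask is empty", "hq_precondition_error")
}

# bright low-saturation pixels: vacuole / tear / background appearance
.bright_mask <- function(pixels, brightness_thresh, max_sat) {
  .rgb_min(pixels) >= brightness_thresh & .rgb_saturation(pixels) < max_sat
}

#' Segment fat vacuoles on an H&E image
#'
#' Candidate pixels are bright, low-saturation pixels inside tissue
#' (intra-tissue white holes). Connected components are kept iff their area is
#' within `[min_vacuole_px, max_vacuole_px]` and their circularity
#' `4*pi*area/perimeter^2` is at least `min_circularity`; the shape filter
#' rejects sinusoids, vessel lumina and tears. Perimeter is the boundary-pixel
#' estimate from EBImage, under which a rasterized disc scores ~1.3 and thin or
#' ragged shapes well below 0.5.
#'
#' @param image an H&E [rgb_image()].
#' @param tissue tissue [binary_mask()] (vacuole holes filled).
#' @param params list with `brightness_thresh`, `max_sat`, `min_vacuole_px`,
#'   `max_vacuole_px`, `min_circularity`; defaults from `cfg$fat`.
#' @param cfg configuration from [hq_config()].
#' @return a [binary_mask()] labelled `"fat"`.
#' @export
segment_fat <- function(image, tissue, params = NULL, cfg = hq_config()) {
  .check_hne_inputs(image, tissue)
  p <- utils::modifyList(cfg$fat, params %||% list())
  if (p$min_vacuole_px >= p$max_vacuole_px)
    .hq_stop("min_vacuole_px must be below max_vacuole_px", "hq_precondition_error")
  cand <- .bright_mask(image$pixels, p$brightness_thresh, p$max_sat) & tissue
  if (!any(cand)) return(binary_mask(cand, label = "fat"))
  lab <- .label_mask(cand)
  fs <- EBImage::computeFeatures.shape(lab)
  area <- fs[, "s.area"]
  circ <- 4 * pi * area / pmax(fs[, "s.perimeter"], 1)^2
  keep <- which(area >= p$min_vacuole_px & area <= p$max_vacuole_px &
                  circ >= p$min_circularity)
  binary_mask(.filter_components(lab, keep), label = "fat")
}

# threshold the hematoxylin (or eosin) density of tissue pixels
.density_threshold <- function(values, method, percentile, side = c("above", "below"),
                               guard) {
  side <- match.arg(side)
  thr <- if (identical(method, "percentile")) {
    stats::quantile(values, percentile / 100, names = FALSE, type = 7)
  } else {
    .otsu_threshold(values)
  }
  if (side == "above") max(thr, guard) else min(thr, guard)
}

#' Segment inflammatory infiltrate on an H&E image
#'
#' With a trained [region_model][train_region_model()], pixels whose
#' inflammation probability reaches `cfg$classifier$decision_threshold` form
#' the mask. Without a model, a rule-based fallback finds dense
#' small-nucleus clusters: hematoxylin density above a threshold (Otsu split of
#' the tissue hematoxylin distribution by default, guarded from below by
#' `od_floor`; a fixed percentile is available via `threshold_method`), closed
#' morphologically, keeping components with at least `min_focus_px` pixels and
#' at least `min_maxima_per_1e4` nuclear local maxima per 10^4 pixels. Portal
#' and lobular infiltrate are not distinguished.
#'
#' @param image an H&E [rgb_image()].
#' @param tissue tissue [binary_mask()].
#' @param model optional region model from [train_region_model()].
#' @param cfg configuration from [hq_config()].
#' @return a [binary_mask()] labelled `"inflammation"`.
#' @export
segment_inflammation <- function(image, tissue, model = NULL, cfg = hq_config()) {
  .check_hne_inputs(image, tissue)
  if (!is.null(model)) {
    pm <- predict_map(model, image, cfg = cfg)
    prob <- .class_prob(pm, "inflammation")
    return(binary_mask(prob >= cfg$classifier$decision_threshold & tissue,
                       label = "inflammation"))
  }
  p <- cfg$inflammation
  h <- unmix_hne(image, cfg)$hematoxylin
  thr <- .density_threshold(h[tissue], p$threshold_method, p$percentile,
                            side = "above", guard = p$od_floor)
  nuclear <- h >= thr & tissue
  if (!any(nuclear)) return(binary_mask(nuclear, label = "inflammation"))
  nuclear <- .close_mask(nuclear, p$close_radius) & tissue
  lab <- .label_mask(nuclear)
  areas <- .component_areas(lab)
  maxima <- .local_maxima(h, radius = p$maxima_radius, floor = p$maxima_floor) & tissue
  mcount <- tabulate(lab[maxima & lab > 0L], nbins = max(lab))
  keep <- which(areas >= p$min_focus_px &
                  mcount / pmax(areas, 1) * 1e4 >= p$min_maxima_per_1e4)
  binary_mask(.filter_components(lab, keep), label = "inflammation")
}

#' Segment ballooned hepatocytes on an H&E image
#'
#' With a trained model, classifier-driven as for
#' [segment_inflammation()]. The fallback rule keeps hepatocyte-scale
#' components (area within `[min_cell_px, max_cell_px]`) of pale, rarefied
#' cytoplasm - eosin density below a threshold (Otsu split of the tissue eosin
#' distribution by default, capped at `od_ceiling`) - that retain a nucleus
#' (at least one hematoxylin local maximum inside). Pixels already claimed as
#' fat or matching the bright vacuole rule are excluded.
#'
#' @param image an H&E [rgb_image()].
#' @param tissue tissue [binary_mask()].
#' @param model optional region model from [train_region_model()].
#' @param fat optional fat [binary_mask()]; computed with [segment_fat()]
#'   defaults when missing.
#' @param cfg configuration from [hq_config()].
#' @return a [binary_mask()] labelled `"ballooning"`.
#' @export
segment_ballooning <- function(image, tissue, model = NULL, fat = NULL,
                               cfg = hq_config()) {
  .check_hne_inputs(image, tissue)
  if (is.null(fat)) fat <- segment_fat(image, tissue, cfg = cfg)
  if (!is.null(model)) {
    pm <- predict_map(model, image, cfg = cfg)
    prob <- .class_prob(pm, "ballooning")
    return(binary_mask(prob >= cfg$classifier$decision_threshold & tissue & !fat,
                       label = "ballooning"))
  }
  p <- cfg$ballooning
  sm <- unmix_hne(image, cfg)
  bright <- .bright_mask(image$pixels, cfg$fat$brightness_thresh, cfg$fat$max_sat)
  eligible <- tissue & !fat & !bright
  if (!any(eligible)) return(binary_mask(eligible & FALSE, label = "ballooning"))
  e <- sm$eosin
  thr <- .density_threshold(e[eligible], p$threshold_method, p$percentile,
                            side = "below", guard = p$od_ceiling)
  pale <- e < thr & eligible
  if (!any(pale)) return(binary_mask(pale, label = "ballooning"))
  lab <- .label_mask(pale)
  areas <- .component_areas(lab)
  keep <- which(areas >= p$min_cell_px & areas <= p$max_cell_px)
  if (isTRUE(p$require_nucleus) && length(keep)) {
    maxima <- .local_maxima(sm$hematoxylin, radius = cfg$inflammation$maxima_radius,
                            floor = cfg$inflammation$maxima_floor)
    mcount <- tabulate(lab[maxima & lab > 0L], nbins = max(lab))
    keep <- keep[mcount[keep] >= 1L]
  }
  binary_mask(.filter_components(lab, keep), label = "ballooning")
}

#' Combine per-feature masks into a quantitative result
#'
#' Masks are made pairwise disjoint with priority fat > inflammation >
#' ballooning (vacuole identity is the most optically certain), then each
#' percentage is `100 * area(mask & tissue) / area(tissue)`. Values are kept at
#' full precision; reports round to 2 decimals.
#'
#' @param masks named list with any of `fat`, `inflammation`, `ballooning`
#'   [binary_mask()]s (missing features count as 0 percent).
#' @param tissue tissue [binary_mask()].
#' @param case_id identifier stamped into the result.
#' @param cfg configuration from [hq_config()].
#' @return object of class `quant_result`: list with `fat_pct`,
#'   `inflammation_pct`, `ballooning_pct`, `cpa_pct` (NA here),
#'   `tissue_area_px`, `case_id`, `method_version`.
#' @export
quantify <- function(masks, tissue, case_id = "case", cfg = hq_config()) {
  ta <- .mask_area(tissue)
  if (ta == 0L) .hq_stop("tissue area is zero", "hq_precondition_error")
  empty <- matrix(FALSE, nrow(tissue), ncol(tissue))
  fat <- masks$fat %||% empty
  infl <- masks$inflammation %||% empty
  ball <- masks$ballooning %||% empty
  for (m in list(fat, infl, ball))
    if (!.same_shape(m, tissue)) .hq_stop("mask shape mismatch", "hq_format_error")
  infl <- infl & !fat
  ball <- ball & !fat & !infl
  structure(list(
    case_id = case_id,
    fat_pct = 100 * sum(fat & tissue) / ta,
    inflammation_pct = 100 * sum(infl & tissue) / ta,
    ballooning_pct = 100 * sum(ball & tissue) / ta,
    cpa_pct = NA_real_,
    tissue_area_px = as.integer(ta),
    method_version = cfg$method_version
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result %s: fat %.2f%%, inflammation %.2f%%, ballooning %.2f%%, CPA %s, tissue %d px>\n",
              x$case_id, x$fat_pct, x$inflammation_pct, x$ballooning_pct,
              if (is.na(x$cpa_pct)) "NA" else sprintf("%.2f%%", x$cpa_pct),
              x$tissue_area_px))
  invisible(x)
}
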