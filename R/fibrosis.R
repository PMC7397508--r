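# Collagen proportionate area on Sirius-red images, with automated
# structural-collagen exclusion (capsule, vessel walls, large tracts).

#' Segment collagen on a Sirius-red image
#'
#' Pixels whose [collagen_signal_sr()] membership reaches
#' `cfg$collagen$signal_thresh` inside tissue, despeckled by dropping
#' components smaller than `cfg$collagen$despeckle_px`.
#'
#' @param image an [rgb_image()] with `stain_kind == "SIRIUS_RED"`.
#' @param tissue tissue [binary_mask()].
#' @param cfg configuration from [hq_config()].
#' @return a [binary_mask()] labelled `"collagen"`.
#' @export
segment_collagen <- function(image, tissue, cfg = hq_config()) {
  stopifnot(inherits(image, "rgb_image"))
  if (image$stain_kind != "SIRIUS_RED")
    .hq_stop(sprintf("expected a SIRIUS_RED image, got stain_kind = %s", image$stain_kind),
             "hq_stain_error")
  if (!.same_shape(image$pixels, tissue))
    .hq_stop("tissue mask shape does not match image", "hq_format_error")
  if (.mask_area(tissue) == 0L)
    .hq_stop("tissue mask is empty", "hq_precondition_error")
  sig <- collagen_signal_sr(image, cfg)$collagen_signal
  mask <- sig >= cfg$collagen$signal_thresh & tissue
  if (any(mask)) {
    lab <- .label_mask(mask)
    keep <- which(.component_areas(lab) >= cfg$collagen$despeckle_px)
    mask <- .filter_components(lab, keep)
  }
  binary_mask(mask, label = "collagen")
}

#' Flag structural (non-fibrotic) collagen components
#'
#' Flags collagen components as structural for exclusion from the CPA:
#' * `capsule` - the component overlaps the tissue-boundary band (tissue within
#'   `capsule_band_px` of the edge) by at least `capsule_overlap_frac` of its
#'   area and is thin (elongation `perimeter^2 / (4*pi*area)` of at least
#'   `min_elongation`);
#' * `vessel_wall` - the component is annular, enclosing a lumen of at least
#'   `lumen_min_px` pixels;
#' * `large_tract` - component area of at least `tract_min_px`.
#' Rules are checked in that order; the first that fires gives the reason.
#'
#' @param collagen collagen [binary_mask()] from [segment_collagen()].
#' @param tissue tissue [binary_mask()].
#' @param params overrides for `cfg$structural`.
#' @param cfg configuration from [hq_config()].
#' @return a [binary_mask()] labelled `"structural"`; attribute `components` is
#'   a data.frame with columns `component`, `area_px`, `reason`.
#' @export
detect_structural_collagen <- function(collagen, tissue, params = NULL,
                                       cfg = hq_config()) {
  if (!.same_shape(collagen, tissue))
    .hq_stop("masks are not aligned", "hq_format_error")
  p <- utils::modifyList(cfg$structural, params %||% list())
  empty <- binary_mask(matrix(FALSE, nrow(tissue), ncol(tissue)), label = "structural")
  attr(empty, "components") <- data.frame(component = integer(0), area_px = integer(0),
                                          reason = character(0))
  if (!any(collagen)) return(empty)
  lab <- .label_mask(collagen)
  fs <- EBImage::computeFeatures.shape(lab)
  area <- fs[, "s.area"]
  elong <- pmax(fs[, "s.perimeter"], 1)^2 / (4 * pi * area)
  band <- tissue & !.erode(tissue, p$capsule_band_px)
  band_overlap <- tabulate(lab[band & lab > 0L], nbins = max(lab))
  # lumen detection: holes fully enclosed by a single component
  filled <- EBImage::fillHull(matrix(as.numeric(collagen), nrow(collagen), ncol(collagen))) > 0.5
  holes <- filled & !collagen
  has_lumen <- rep(FALSE, max(lab))
  if (any(holes)) {
    hlab <- .label_mask(holes)
    hareas <- .component_areas(hlab)
    for (hid in which(hareas >= p$lumen_min_px)) {
      ring <- .dilate(hlab == hid, 1) & collagen
      owner <- unique(lab[ring & lab > 0L])
      if (length(owner) >= 1L) has_lumen[owner] <- TRUE
    }
  }
  reason <- rep(NA_character_, max(lab))
  is_capsule <- band_overlap / area >= p$capsule_overlap_frac & elong >= p$min_elongation
  reason[is_capsule] <- "capsule"
  reason[is.na(reason) & has_lumen] <- "vessel_wall"
  reason[is.na(reason) & area >= p$tract_min_px] <- "large_tract"
  flagged <- which(!is.na(reason))
  out <- binary_mask(.filter_components(lab, flagged), label = "structural")
  attr(out, "components") <- data.frame(component = flagged,
                                        area_px = as.integer(area[flagged]),
                                        reason = reason[flagged])
  out
}

#' Collagen proportionate area after structural exclusion
#'
#' `cpa_pct = 100 * area((collagen \ structural) & tissue) / area(tissue)`.
#' Growing the structural mask can only decrease the CPA.
#'
#' @param collagen collagen [binary_mask()].
#' @param structural structural [binary_mask()] (e.g. from
#'   [detect_structural_collagen()], or a user-supplied override mask).
#' @param tissue tissue [binary_mask()].
#' @param case_id identifier stamped into the result.
#' @param cfg configuration from [hq_config()].
#' @return object of class `cpa_result`: list with `cpa_pct`,
#'   `collagen_area_px`, `structural_area_px`, `tissue_area_px`,
#'   `structural_components` (data.frame of reasons, when available).
#' @export
compute_cpa <- function(collagen, structural, tissue, case_id = "case",
                        cfg = hq_config()) {
  if (!.same_shape(collagen, tissue) || !.same_shape(structural, tissue))
    .hq_stop("masks are not aligned", "hq_format_error")
  ta <- .mask_area(tissue)
  if (ta == 0L) .hq_stop("tissue area is zero", "hq_precondition_error")
  kept <- collagen & !structural & tissue
  structure(list(
    case_id = case_id,
    cpa_pct = 100 * sum(kept) / ta,
    collagen_area_px = as.integer(sum(collagen & tissue)),
    structural_area_px = as.integer(sum(structural & collagen & tissue)),
    tissue_area_px = as.integer(ta),
    structural_components = attr(structural, "components"),
    method_version = cfg$method_version
  ), class = "cpa_result")
}

#' @export
print.cpa_result <- function(x, ...) {
  cat(sprintf("<cpa_result %s: CPA %.2f%% (collagen %d px, structural %d px, tissue %d px)>\n",
              x$case_id, x$cpa_pct, x$collagen_area_px, x$structural_area_px,
              x$tissue_area_px))
  invisible(x)
}
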