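#' Default configuration for the quantitation pipeline
#'
#' All tunable constants of the pipeline live in one nested list: tissue-mask
#' thresholds, stain vectors and the Sirius-red hue band, the fat / inflammation
#' / ballooning segmentation parameters, structural-collagen rules, the
#' published scoring constants, and classifier hyperparameters. Layering is
#' built-in defaults < YAML config file < explicit overrides; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param file optional path to a YAML file whose keys override the defaults.
#' @param overrides optional nested list of overrides applied after `file`.
#' @return a nested list of settings with class `hq_config`.
#' @examples
#' cfg <- hq_config(overrides = list(fat = list(min_circularity = 0.6)))
#' cfg$fat$min_circularity
#' @export
hq_config <- function(file = NULL, overrides = NULL) {
  cfg <- .hq_defaults()
  if (!is.null(file)) {
    if (!file.exists(file)) .hq_stop(sprintf("config file not found: %s", file), "hq_io_error")
    cfg <- .merge_config(cfg, yaml::read_yaml(file), path = "")
  }
  if (!is.null(overrides)) cfg <- .merge_config(cfg, overrides, path = "")
  class(cfg) <- c("hq_config", "list")
  cfg
}

.hq_defaults <- function() {
  list(
    method_version = "hepaquant-0.1.0",
    tissue = list(
      bg_min_rgb = 220,        # pixel is background iff min(R,G,B) >= this ...
      bg_max_sat = 0.08,       # ... and saturation below this (8-bit scale)
      min_component_px = 256,  # at 1 um/px; rescaled by pixel_size_um^-2
      max_hole_px = 50000      # interior holes up to this size count as tissue
    ),
    stains = list(
      # optical-density stain vectors (Ruifrok-Johnston convention), normalized
      # at use time
      hematoxylin = c(0.65, 0.70, 0.29),
      eosin = c(0.07, 0.99, 0.11),
      # Sirius-red hue band: full membership for hue in [-lo, +hi] degrees
      # (wrapping through 0 = red), linear ramps outside
      sr_hue_lo = -30, sr_hue_hi = 25, sr_hue_ramp = 10,
      sr_sat_min = 0.35, sr_sat_ramp = 0.1,
      sr_val_min = 0.2, sr_val_ramp = 0.1
    ),
    fat = list(
      brightness_thresh = 200, # min(R,G,B) of a vacuole candidate pixel
      max_sat = 0.15,
      min_vacuole_px = 30,
      max_vacuole_px = 15000,
      min_circularity = 0.55   # 4*pi*area/perimeter^2, boundary-pixel perimeter
    ),
    inflammation = list(
      threshold_method = "otsu",  # or "percentile"
      percentile = 97,            # used when threshold_method = "percentile"
      od_floor = 0.30,            # nuclear pixels must exceed this OD
      close_radius = 2,
      min_focus_px = 150,
      min_maxima_per_1e4 = 20,    # nuclear maxima density of a kept component
      maxima_radius = 2,
      maxima_floor = 0.6
    ),
    ballooning = list(
      threshold_method = "otsu",
      percentile = 30,
      od_ceiling = 0.45,          # pale-cytoplasm threshold never above this
      min_cell_px = 400,
      max_cell_px = 5000,
      require_nucleus = TRUE
    ),
    collagen = list(
      signal_thresh = 0.5,
      despeckle_px = 16
    ),
    structural = list(
      capsule_band_px = 20,       # width of the tissue-boundary band
      capsule_overlap_frac = 0.25,
      min_elongation = 4,         # thinness: perimeter^2 / (4*pi*area)
      lumen_min_px = 300,
      tract_min_px = 20000
    ),
    scoring = list(
      w_fat = 0.058, w_ballooning = 0.079, w_inflammation = 0.485,
      intercept = -3.882,
      nash_cutoff = 0.31,
      cpa_cutoffs = c(F2 = 2.05, F3 = 3.1, F4 = 8.1)
    ),
    classifier = list(
      n_trees = 200,
      max_depth = 12,
      tile_px = 8,
      min_purity = 0.6,
      min_tiles_per_class = 50,
      decision_threshold = 0.5,
      large_window = 25,          # second scale for context features
      feature_version = "hqfeat-1"
    ),
    synth = list(
      noise_sd = 4,
      tissue_frac = 0.60,
      rejection_tol = 0.03,
      max_attempts = 50
    )
  )
}

.merge_config <- function(base, over, path) {
  if (!is.list(over)) .hq_stop(sprintf("config node '%s' must be a list", path), "hq_config_error")
  nm <- names(over)
  if (length(over) && (is.null(nm) || any(nm == "")))
    .hq_stop(sprintf("config node '%s' has unnamed entries", path), "hq_config_error")
  for (key in nm) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      .hq_stop(sprintf("unknown config key '%s'", full), "hq_config_error")
    if (is.list(base[[key]])) {
      base[[key]] <- .merge_config(base[[key]], over[[key]], full)
    } else {
      base[[key]] <- over[[key]]
    }
  }
  base
}

#' Fingerprint of a resolved configuration
#'
#' A short deterministic hash stamped into every report so outputs can be
#' traced back to the exact settings that produced them.
#'
#' @param cfg a configuration from [hq_config()].
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(cfg) .hq_hash(unclass(cfg))
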