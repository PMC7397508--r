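# End-to-end case and cohort runners: tissue -> stain -> segment -> quantify
# -> score, with JSON/CSV reporting.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .hq_stop(sprintf("[%s] %s", name, conditionMessage(e)), "hq_stage_error"))
}

.as_image <- function(x, stain_kind) {
  if (inherits(x, "rgb_image")) return(x)
  load_image(x, stain_kind = stain_kind)
}

#' Run the full quantitation pipeline on one case
#'
#' Executes tissue masking, H&E segmentation of fat / inflammation /
#' ballooning, optional Sirius-red collagen quantitation with structural
#' exclusion, and scoring (combined NASH score, NASH call, fibrosis band).
#' Fully automated: no step needs manual input; a user-supplied structural
#' mask can optionally override the automatic structural-collagen detection.
#'
#' @param hne H&E image: an [rgb_image()] or a file path.
#' @param sr optional Sirius-red image ([rgb_image()] or path); when absent the
#'   CPA fields are `NA` and no fibrosis band is assigned.
#' @param model optional [region_model][train_region_model()] used for
#'   inflammation and ballooning; the rule-based fallback is used otherwise.
#' @param structural_mask optional user [binary_mask()] overriding automatic
#'   structural-collagen detection.
#' @param case_id identifier.
#' @param cfg configuration from [hq_config()].
#' @param out optional path for a JSON report (percentages rounded to 2
#'   decimals, statistics to 3; a full-precision sidecar is written next to it
#'   with suffix `.full.json`).
#' @param save_masks optional directory to receive per-feature PNG masks.
#' @return case report list with `quant` (a [quantify()] result including
#'   `cpa_pct`), `combined_score`, `nash`, `fibrosis_band`, `timings_s`,
#'   `method_version`, `config_hash`.
#' @export
run_case <- function(hne, sr = NULL, model = NULL, structural_mask = NULL,
                     case_id = "case", cfg = hq_config(), out = NULL,
                     save_masks = NULL) {
  t0 <- proc.time()[[3L]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[[3L]]
    timings[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  hne_img <- .stage("load_image", .as_image(hne, "HE"))
  tick("load")
  tissue <- .stage("tissue_mask", compute_tissue_mask(hne_img, cfg = cfg))
  fat <- .stage("segment_fat", segment_fat(hne_img, tissue, cfg = cfg))
  infl <- .stage("segment_inflammation",
                 segment_inflammation(hne_img, tissue, model = model, cfg = cfg))
  ball <- .stage("segment_ballooning",
                 segment_ballooning(hne_img, tissue, model = model, fat = fat, cfg = cfg))
  quant <- .stage("quantify",
                  quantify(list(fat = fat, inflammation = infl, ballooning = ball),
                           tissue, case_id = case_id, cfg = cfg))
  tick("hne")
  cpa <- NULL
  if (!is.null(sr)) {
    sr_img <- .stage("load_image", .as_image(sr, "SIRIUS_RED"))
    sr_tissue <- .stage("tissue_mask", compute_tissue_mask(sr_img, cfg = cfg))
    coll <- .stage("segment_collagen", segment_collagen(sr_img, sr_tissue, cfg = cfg))
    struct <- if (!is.null(structural_mask)) structural_mask else
      .stage("detect_structural", detect_structural_collagen(coll, sr_tissue, cfg = cfg))
    cpa <- .stage("compute_cpa",
                  compute_cpa(coll, struct, sr_tissue, case_id = case_id, cfg = cfg))
    quant$cpa_pct <- cpa$cpa_pct
  }
  tick("sr")
  score <- combined_nash_score(quant$fat_pct, quant$ballooning_pct,
                               quant$inflammation_pct, cfg = cfg)
  band <- if (is.null(cpa)) NA_character_ else
    as.character(fibrosis_band_from_cpa(cpa$cpa_pct, cfg = cfg))
  report <- list(case_id = case_id, quant = quant,
                 combined_score = score, nash = classify_nash(score, cfg),
                 fibrosis_band = band,
                 structural_components = if (is.null(cpa)) NULL else cpa$structural_components,
                 timings_s = as.list(timings),
                 method_version = cfg$method_version,
                 config_hash = config_hash(cfg))
  if (!is.null(save_masks)) {
    dir.create(save_masks, showWarnings = FALSE, recursive = TRUE)
    write_mask_png(tissue, file.path(save_masks, paste0(case_id, "_tissue.png")))
    write_mask_png(fat, file.path(save_masks, paste0(case_id, "_fat.png")))
    write_mask_png(infl, file.path(save_masks, paste0(case_id, "_inflammation.png")))
    write_mask_png(ball, file.path(save_masks, paste0(case_id, "_ballooning.png")))
  }
  if (!is.null(out)) .write_case_json(report, out)
  report
}

.round_report <- function(report) {
  q <- report$quant
  list(case_id = report$case_id,
       fat_pct = round(q$fat_pct, 2), inflammation_pct = round(q$inflammation_pct, 2),
       ballooning_pct = round(q$ballooning_pct, 2),
       cpa_pct = if (is.na(q$cpa_pct)) NULL else round(q$cpa_pct, 2),
       tissue_area_px = q$tissue_area_px,
       combined_score = round(report$combined_score, 3),
       nash = report$nash, fibrosis_band = report$fibrosis_band,
       method_version = report$method_version, config_hash = report$config_hash)
}

.write_case_json <- function(report, out) {
  ok <- FALSE
  on.exit(if (!ok) unlink(c(out, paste0(out, ".full.json"))), add = TRUE)
  jsonlite::write_json(.round_report(report), out, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  full <- report
  full$quant <- unclass(full$quant)
  jsonlite::write_json(full, paste0(out, ".full.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  ok <- TRUE
  invisible(out)
}

#' Run the pipeline over a cohort manifest
#'
#' The manifest (data.frame or CSV path) lists one case per row: `case_id`,
#' `hne_path`, optional `sr_path`, and optionally the NASH CRN columns
#' `steatosis_grade`, `lobular_inflammation`, `ballooning`, `fibrosis_stage`.
#' Cases are processed in deterministic `case_id` order. When CRN scores are
#' present the per-grade median/IQR table and trend statistics (Spearman rho
#' and Jonckheere-Terpstra per feature) are added.
#'
#' @param manifest data.frame or CSV path.
#' @param model optional [region_model][train_region_model()].
#' @param cfg configuration from [hq_config()].
#' @param out_dir optional directory for `results.csv`, `summary_table.csv` and
#'   per-case JSON reports.
#' @return list with `results` (per-case data.frame), `reports`, and when CRN
#'   scores are present `table` ([summarize_by_grade()]) and `trend`.
#' @export
run_cohort <- function(manifest, model = NULL, cfg = hq_config(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (is.null(manifest$case_id) || is.null(manifest$hne_path))
    .hq_stop("manifest needs case_id and hne_path columns", "hq_manifest_error")
  if (anyDuplicated(manifest$case_id))
    .hq_stop(sprintf("duplicate case_id in manifest: %s",
                     manifest$case_id[duplicated(manifest$case_id)][1L]),
             "hq_manifest_error")
  manifest <- manifest[order(manifest$case_id), , drop = FALSE]
  reports <- lapply(seq_len(nrow(manifest)), function(i) {
    srp <- manifest$sr_path[i]
    if (!is.null(srp) && (is.na(srp) || !nzchar(srp))) srp <- NULL
    run_case(manifest$hne_path[i], sr = srp, model = model,
             case_id = manifest$case_id[i], cfg = cfg)
  })
  results <- do.call(rbind, lapply(reports, function(r) {
    df <- as.data.frame(r$quant)
    df$combined_score <- r$combined_score
    df$nash <- r$nash
    df$fibrosis_band <- r$fibrosis_band
    df
  }))
  out <- list(results = results, reports = reports)
  crn_cols <- c("steatosis_grade", "lobular_inflammation", "ballooning", "fibrosis_stage")
  if (all(crn_cols %in% names(manifest))) {
    scores <- manifest[, c("case_id", crn_cols)]
    out$table <- summarize_by_grade(results, scores)
    out$trend <- .trend_stats(results, scores)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    num <- vapply(results, is.numeric, TRUE)
    res_out <- results
    res_out[num] <- lapply(res_out[num], function(x) round(x, 2))
    utils::write.csv(res_out, file.path(out_dir, "results.csv"), row.names = FALSE)
    if (!is.null(out$table)) {
      tab <- out$table
      tab[c("median", "q1", "q3")] <- lapply(tab[c("median", "q1", "q3")], round, 2)
      utils::write.csv(tab, file.path(out_dir, "summary_table.csv"), row.names = FALSE)
    }
    for (r in reports)
      .write_case_json(r, file.path(out_dir, paste0(r$case_id, ".json")))
  }
  out
}

.trend_stats <- function(results, scores) {
  pairs <- list(c("fat_pct", "steatosis_grade"),
                c("inflammation_pct", "lobular_inflammation"),
                c("ballooning_pct", "ballooning"),
                c("cpa_pct", "fibrosis_stage"))
  rows <- list()
  for (pr in pairs) {
    v <- results[[pr[1L]]]; g <- scores[[pr[2L]]]
    if (is.null(v) || is.null(g)) next
    ok <- is.finite(v) & !is.na(g)
    if (sum(ok) < 3L) next
    grank <- as.integer(factor(as.character(g[ok]),
                               levels = sort(unique(as.character(g[ok])))))
    rho <- suppressWarnings(stats::cor(v[ok], grank, method = "spearman"))
    groups <- split(v[ok], grank)
    jt <- if (length(groups) >= 3L) jonckheere_terpstra(groups) else NULL
    rows[[length(rows) + 1L]] <- data.frame(
      feature = pr[1L], scale = pr[2L], spearman_rho = rho,
      jtt_z = if (is.null(jt)) NA_real_ else jt$z,
      jtt_p = if (is.null(jt)) NA_real_ else jt$p,
      jtt_method = if (is.null(jt)) NA_character_ else jt$method)
  }
  do.call(rbind, rows)
}
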