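# End-to-end orchestration: preprocess the image quartet (S_O, S_POI, H_O,
# H_A), register specimen to histology, carry the POI measurement areas
# into histology space, and emit the tissue-label report with full
# parameter/seed logging for reproducible runs.

#' Pipeline run configuration
#'
#' @param s_o,s_poi paths to the specimen snapshot PPMs (without / with
#'   projected POIs).
#' @param h_o path to the histology image (PGM or PPM).
#' @param annotation path to the annotated class raster (see
#'   [write_annotation]).
#' @param out_dir output run directory (created if missing).
#' @param poi_radius probe radius in px (default 5).
#' @param bins,lambda,levels,spacing,seed registration parameters, see
#'   [reg_config].
#' @param fixed_histology if TRUE (default, the recommended orientation)
#'   histology is the fixed image and the specimen snapshot moves; FALSE
#'   swaps them.
#' @return a list of class `run_config`.
#' @export
run_config <- function(s_o, s_poi, h_o, annotation, out_dir,
                       poi_radius = 5, bins = 32L, lambda = 0.05,
                       levels = 3L, spacing = 16L, seed = 0L,
                       fixed_histology = TRUE) {
  cfg <- list(s_o = s_o, s_poi = s_poi, h_o = h_o, annotation = annotation,
              out_dir = out_dir, poi_radius = poi_radius, bins = bins,
              lambda = lambda, levels = levels, spacing = spacing,
              seed = seed, fixed_histology = fixed_histology)
  for (f in c("s_o", "s_poi", "h_o", "annotation"))
    if (!file.exists(cfg[[f]])) stopf("run_config: missing input '%s': %s", f, cfg[[f]])
  structure(cfg, class = "run_config")
}

pipeline_stage <- function(name, log_con, expr) {
  res <- tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  cat(sprintf("[%s] stage %s: ok\n", format(Sys.time(), "%H:%M:%S"), name),
      file = log_con, append = TRUE)
  res
}

#' Run the full validation pipeline
#'
#' Stages: preprocessing (grayscale conversion and resampling to the
#' registration grid), registration (DDF estimation with MI loss, metrics),
#' poi_detection, label_extraction. All outputs, parameters and seeds land
#' in `config$out_dir`; on error the failing stage is named and partial
#' outputs are retained.
#'
#' @param config a [run_config].
#' @return the run directory path (invisibly); outputs include
#'   `metrics.json`, `ddf.txt`, `labels.csv`, `pois.csv`, `warped.pgm`,
#'   `overlay.pgm`, `log.txt`, `config.json`.
#' @export
run_full_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.txt")
  cat(sprintf("ppmap pipeline run, seed %d\n", config$seed), file = log_path)
  jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  rc <- reg_config(bins = config$bins, lambda = config$lambda,
                   levels = config$levels, spacing = config$spacing,
                   seed = config$seed)

  pre <- pipeline_stage("preprocessing", log_path, {
    s_o <- read_pnm(config$s_o)
    s_poi <- read_pnm(config$s_poi)
    h_raw <- read_pnm(config$h_o)
    if (!inherits(s_o, "rgb_image") || !inherits(s_poi, "rgb_image"))
      stopf("specimen snapshots must be RGB (P3)")
    h_gray <- if (inherits(h_raw, "rgb_image")) to_luminance_gray(h_raw) else h_raw
    s_gray <- to_saturation_gray(s_o)
    list(s_o = s_o, s_poi = s_poi,
         s_gray = resize_input(s_gray, rc$width, rc$height),
         h_gray = resize_input(h_gray, rc$width, rc$height))
  })

  reg <- pipeline_stage("registration", log_path, {
    if (config$fixed_histology) estimate_ddf(pre$h_gray, pre$s_gray, rc)
    else estimate_ddf(pre$s_gray, pre$h_gray, rc)
  })
  write_ddf(reg$field, file.path(config$out_dir, "ddf.txt"))
  write_pnm(reg$warped, file.path(config$out_dir, "warped.pgm"))
  metrics <- list(mi_before = reg$mi_before, mi_after = reg$mi_after,
                  dice_before = reg$dice_before, dice_after = reg$dice_after,
                  converged = reg$converged, seed = config$seed)
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  pois <- pipeline_stage("poi_detection", log_path, {
    # POIs live in snapshot space; detection runs at native resolution,
    # centers are then rescaled to the registration grid.
    p <- detect_pois(pre$s_poi, pre$s_o, radius = config$poi_radius)
    sc_x <- rc$width / ncol(as_gray_matrix(to_luminance_gray(pre$s_o)))
    sc_y <- rc$height / nrow(as_gray_matrix(to_luminance_gray(pre$s_o)))
    poi_set(cbind(p$centers[, 1] * sc_x, p$centers[, 2] * sc_y),
            radius = config$poi_radius, shape = c(rc$height, rc$width))
  })
  write.csv(data.frame(id = seq_len(nrow(pois$centers)),
                       x = pois$centers[, 1], y = pois$centers[, 2]),
            file.path(config$out_dir, "pois.csv"), row.names = FALSE)

  report <- pipeline_stage("label_extraction", log_path, {
    ann <- read_annotation(config$annotation)
    mask <- rasterize_poi_areas(pois, dim(ann$labels))
    warped_mask <- warp_poi_mask(mask, reg$field)
    extract_labels(warped_mask, ann)
  })
  write.csv(as.data.frame(report), file.path(config$out_dir, "labels.csv"),
            row.names = FALSE)
  jsonlite::write_json(split(as.data.frame(report)[c("class", "percent")],
                             as.data.frame(report)$poi_id),
                       file.path(config$out_dir, "labels.json"),
                       auto_unbox = TRUE, digits = NA)

  # overlay figure: annotation codes with warped POI disks burned in bright
  ann <- read_annotation(config$annotation)
  mask <- rasterize_poi_areas(pois, dim(ann$labels))
  warped_mask <- warp_poi_mask(mask, reg$field)
  ov <- ann$labels / max(1L, max(ann$labels)) * 0.6
  ov[warped_mask > 0L] <- 1
  write_pnm(gray_image(ov), file.path(config$out_dir, "overlay.pgm"))

  cat("done\n", file = log_path, append = TRUE)
  invisible(config$out_dir)
}

#' Summarize a cohort of pipeline runs
#'
#' Reads `metrics.json` from each run directory and reports per-run metrics
#' plus the cohort median and interquartile range of Dice and MI, before and
#' after registration.
#'
#' @param run_dirs character vector of run directories (>= 1).
#' @param out_csv optional path for the per-run table.
#' @return a data.frame of per-run metrics with a `summary` attribute
#'   (data.frame of median and IQR per metric).
#' @export
evaluate_cohort <- function(run_dirs, out_csv = NULL) {
  if (length(run_dirs) < 1L) stopf("evaluate_cohort: no runs given")
  rows <- lapply(run_dirs, function(d) {
    m <- jsonlite::read_json(file.path(d, "metrics.json"), simplifyVector = TRUE)
    data.frame(run = d, dice_before = m$dice_before, dice_after = m$dice_after,
               mi_before = m$mi_before, mi_after = m$mi_after)
  })
  tab <- do.call(rbind, rows)
  metrics <- c("dice_before", "dice_after", "mi_before", "mi_after")
  summ <- do.call(rbind, lapply(metrics, function(mm) {
    v <- tab[[mm]]
    data.frame(metric = mm, median = median(v),
               iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)))
  }))
  if (!is.null(out_csv)) write.csv(tab, out_csv, row.names = FALSE)
  attr(tab, "summary") <- summ
  tab
}
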