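# POI detection and histology label transfer.
#
# Measurement locations are projected onto the specimen as light dots; their
# centers are recovered from the difference between the snapshot with dots
# (S_POI) and without (S_O), rasterized as probe-sized disks, carried into
# histology space by the registration's displacement field, and intersected
# with the pathologist's annotation raster to yield per-location tissue
# percentages.

#' Point-of-interest set
#'
#' @param centers n x 2 matrix (or data.frame) of 0-based (x, y) pixel
#'   coordinates in S_POI space; pairwise distinct.
#' @param radius probe radius in pixels (> 0).
#' @param shape optional c(height, width) for bounds checking.
#' @return an object of class `poi_set`.
#' @export
poi_set <- function(centers, radius, shape = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L || nrow(centers) < 1L)
    stopf("poi_set: centers must be a non-empty n x 2 (x, y) matrix")
  if (any(!is.finite(centers))) stopf("poi_set: non-finite centers")
  if (!is.numeric(radius) || radius <= 0) stopf("poi_set: radius must be > 0")
  if (anyDuplicated(round(centers, 6)) > 0L) stopf("poi_set: duplicate centers")
  if (!is.null(shape)) {
    if (any(centers[, 1] < 0 | centers[, 1] > shape[2] - 1 |
            centers[, 2] < 0 | centers[, 2] > shape[1] - 1))
      stopf("poi_set: center outside image bounds")
  }
  colnames(centers) <- c("x", "y")
  structure(list(centers = centers, radius = radius), class = "poi_set")
}

#' @export
print.poi_set <- function(x, ...) {
  cat(sprintf("<poi_set: %d centers, probe radius %.1f px>\n",
              nrow(x$centers), x$radius))
  invisible(x)
}

#' Detect projected POI dots from a snapshot pair
#'
#' Thresholds the luminance difference S_POI - S_O at mean + k SD (the dots
#' cover a negligible image fraction, so global statistics approximate the
#' background), labels 4-connected components, drops components smaller than
#' `min_area`, and returns component centroids. Components more than twice
#' the median area trigger a merged-blob warning.
#'
#' @param s_poi,s_o [rgb_image]s of equal dimensions, acquired back-to-back
#'   (same camera pose).
#' @param radius probe radius (px) recorded on the returned [poi_set];
#'   default 5.
#' @param min_area minimum component area in px (default 5).
#' @param k_sd threshold multiplier (default 3).
#' @return a [poi_set].
#' @export
detect_pois <- function(s_poi, s_o, radius = 5, min_area = 5L, k_sd = 3) {
  if (!inherits(s_poi, "rgb_image") || !inherits(s_o, "rgb_image"))
    stopf("detect_pois: need rgb_image inputs")
  if (!all(dim(s_poi) == dim(s_o))) stopf("detect_pois: dimension mismatch")
  d <- as_gray_matrix(to_luminance_gray(s_poi)) -
       as_gray_matrix(to_luminance_gray(s_o))
  thr <- mean(d) + k_sd * sd(d)
  bw <- matrix(as.integer(d > thr), nrow(d), ncol(d))
  lab <- cpp_label_components(bw)
  k <- max(lab)
  if (k == 0L) stopf("detect_pois: no POI dots detected")
  areas <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) stopf("detect_pois: no components of at least %d px", min_area)
  med_area <- median(areas[keep])
  big <- keep[areas[keep] > 2 * med_area]
  if (length(big) > 0L)
    warning(sprintf("detect_pois: possible merged/overlapping dots (components %s)",
                    paste(big, collapse = ", ")))
  centers <- t(vapply(keep, function(l) {
    idx <- which(lab == l)
    y <- (idx - 1L) %% nrow(lab)
    x <- (idx - 1L) %/% nrow(lab)
    c(mean(x), mean(y))
  }, numeric(2)))
  poi_set(centers, radius = radius, shape = dim(d))
}

#' Rasterize POI measurement areas as indexed disks
#'
#' Each POI becomes a disk of the probe radius around its center; pixel
#' membership is decided by the pixel-center-inside-circle rule
#' (x - cx)^2 + (y - cy)^2 <= r^2. Disks must lie fully inside the image and
#' must not overlap (measurement areas are distinct).
#'
#' @param pois a [poi_set].
#' @param shape c(height, width) of the target raster.
#' @return integer matrix; value k > 0 marks POI k's disk, 0 elsewhere.
#' @export
rasterize_poi_areas <- function(pois, shape) {
  if (!inherits(pois, "poi_set")) stopf("rasterize_poi_areas: need a poi_set")
  H <- shape[1]; W <- shape[2]
  r <- pois$radius
  out <- matrix(0L, H, W)
  for (k in seq_len(nrow(pois$centers))) {
    cx <- pois$centers[k, 1]; cy <- pois$centers[k, 2]
    if (cx - r < 0 || cx + r > W - 1 || cy - r < 0 || cy + r > H - 1)
      stopf("rasterize_poi_areas: disk %d exceeds image bounds", k)
    xs <- floor(cx - r):ceiling(cx + r)
    ys <- floor(cy - r):ceiling(cy + r)
    for (x in xs) for (y in ys) {
      if ((x - cx)^2 + (y - cy)^2 <= r^2) {
        if (out[y + 1L, x + 1L] != 0L)
          stopf("rasterize_poi_areas: disks %d and %d overlap",
                out[y + 1L, x + 1L], k)
        out[y + 1L, x + 1L] <- k
      }
    }
  }
  out
}

#' Warp an indexed POI mask into histology space
#'
#' Applies the same backward-warp convention as [warp] with nearest-neighbor
#' sampling, so integer label codes are preserved (never interpolated).
#'
#' @param mask integer raster of POI indices (0 = background).
#' @param field a [displacement_field] of matching dimensions.
#' @return the warped integer raster.
#' @export
warp_poi_mask <- function(mask, field) {
  if (!inherits(field, "displacement_field")) stopf("warp_poi_mask: need a displacement_field")
  if (!all(dim(mask) == dim(field$u))) stopf("warp_poi_mask: dimension mismatch")
  storage.mode(mask) <- "integer"
  cpp_warp_nearest(mask, field$u, field$v)
}

#' Annotation map constructor
#'
#' Integer-coded class raster in histology space plus a legend mapping each
#' code to a tissue class name (pathologist ground truth).
#'
#' @param labels integer matrix of class codes.
#' @param legend named character vector; names are the integer codes as
#'   strings, values the class names (e.g. `c("0" = "background",
#'   "1" = "fat", "2" = "connective", "3" = "invasive carcinoma")`).
#' @return an object of class `annotation_map`.
#' @export
annotation_map <- function(labels, legend) {
  if (!is.matrix(labels)) stopf("annotation_map: labels must be a matrix")
  storage.mode(labels) <- "integer"
  codes <- sort(unique(as.vector(labels)))
  if (!all(as.character(codes) %in% names(legend)))
    stopf("annotation_map: raster codes missing from legend: %s",
          paste(setdiff(as.character(codes), names(legend)), collapse = ", "))
  structure(list(labels = labels, legend = legend), class = "annotation_map")
}

#' Per-POI tissue-type percentages from annotated histology
#'
#' Overlays warped POI disks on the annotation raster and reports, for each
#' POI, the percentage of its (histology-space) disk pixels carrying each
#' annotated class — every legend class is reported, including 0%. POIs
#' whose disk is entirely background, or whose disk vanished during
#' warping, are flagged, never dropped.
#'
#' @param warped_mask integer POI raster in histology space (see
#'   [warp_poi_mask]).
#' @param annotation an [annotation_map] of equal dimensions.
#' @param background_code integer code treated as unannotated background
#'   (default 0).
#' @return an object of class `tissue_label_report`: a data.frame with
#'   columns poi_id, class, percent, plus a `flags` attribute
#'   (data.frame poi_id, flag).
#' @export
extract_labels <- function(warped_mask, annotation, background_code = 0L) {
  if (!inherits(annotation, "annotation_map")) stopf("extract_labels: need an annotation_map")
  if (!all(dim(warped_mask) == dim(annotation$labels)))
    stopf("extract_labels: dimension mismatch")
  ids <- setdiff(sort(unique(as.vector(warped_mask))), 0L)
  classes <- annotation$legend
  rows <- list()
  flags <- list()
  for (k in ids) {
    sel <- warped_mask == k
    n <- sum(sel)
    if (n == 0L) next
    lab <- annotation$labels[sel]
    for (code in names(classes)) {
      pct <- 100 * sum(lab == as.integer(code)) / n
      rows[[length(rows) + 1L]] <- data.frame(
        poi_id = k, class = unname(classes[code]), percent = pct,
        stringsAsFactors = FALSE)
    }
    if (all(lab == background_code))
      flags[[length(flags) + 1L]] <- data.frame(
        poi_id = k, flag = "all_background", stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(poi_id = integer(0), flag = character(0))
  structure(report, flags = flags, class = c("tissue_label_report", "data.frame"))
}

#' @export
print.tissue_label_report <- function(x, ...) {
  cat(sprintf("<tissue_label_report: %d POIs x %d classes>\n",
              length(unique(x$poi_id)), length(unique(x$class))))
  print.data.frame(x, ...)
  fl <- attr(x, "flags")
  if (nrow(fl) > 0L) {
    cat("flags:\n"); print.data.frame(fl)
  }
  invisible(x)
}
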