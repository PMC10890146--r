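# Image containers and preprocessing for registration input.
#
# An RGB image is an H x W x 3 array with intensities in [0, 1]; a gray
# image is an H x W matrix in [0, 1]. The specimen snapshot is converted to
# grayscale via the HSV saturation channel (which gives histology-like
# intensity levels on H&E-stained tissue), the histology image via Rec. 709
# luminance, and both are resampled to the fixed 256 x 192 registration grid.

#' RGB image constructor
#'
#' @param pixels H x W x 3 numeric array. Values in 0..255 are rescaled to
#'   [0, 1]; values already in [0, 1] are kept.
#' @return an array of class `rgb_image` with values in [0, 1].
#' @export
rgb_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("rgb_image: need an H x W x 3 array")
  if (any(dim(pixels)[1:2] < 1L)) stopf("rgb_image: dimensions must be positive")
  if (any(!is.finite(pixels))) stopf("rgb_image: non-finite pixels")
  mx <- max(pixels)
  if (mx > 1) pixels <- pixels / 255
  if (min(pixels) < 0 || max(pixels) > 1)
    stopf("rgb_image: intensities outside [0, 1] after rescaling")
  structure(pixels, class = "rgb_image")
}

#' Gray image constructor
#' @param pixels H x W numeric matrix with values in [0, 1].
#' @return a matrix of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stopf("gray_image: need a matrix")
  if (any(dim(pixels) < 1L)) stopf("gray_image: dimensions must be positive")
  if (any(!is.finite(pixels))) stopf("gray_image: non-finite pixels")
  if (min(pixels) < -1e-12 || max(pixels) > 1 + 1e-12)
    stopf("gray_image: intensities must lie in [0, 1]")
  pixels[pixels < 0] <- 0; pixels[pixels > 1] <- 1
  structure(pixels, class = c("gray_image", "matrix", "array"))
}

as_gray_matrix <- function(img) {
  if (inherits(img, "gray_image")) return(unclass(img))
  if (is.matrix(img) && is.numeric(img)) return(img)
  stopf("expected a gray_image or numeric matrix")
}

#' Saturation-channel grayscale conversion
#'
#' Returns the HSV saturation channel S = (max - min) / max (S = 0 where
#' max = 0). On specimen snapshots this yields intensity levels comparable
#' to the grayscale histology image, which keeps the mutual-information
#' objective informative across the two modalities.
#'
#' @param img an [rgb_image].
#' @return a [gray_image].
#' @export
to_saturation_gray <- function(img) {
  if (!inherits(img, "rgb_image")) stopf("to_saturation_gray: need an rgb_image")
  a <- unclass(img)
  mx <- pmax(a[, , 1], a[, , 2], a[, , 3])
  mn <- pmin(a[, , 1], a[, , 2], a[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  gray_image(matrix(s, dim(a)[1], dim(a)[2]))
}

#' Luminance grayscale conversion (Rec. 709 weights)
#'
#' @param img an [rgb_image].
#' @return a [gray_image] 0.2126 R + 0.7152 G + 0.0722 B.
#' @export
to_luminance_gray <- function(img) {
  if (!inherits(img, "rgb_image")) stopf("to_luminance_gray: need an rgb_image")
  a <- unclass(img)
  g <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
  gray_image(matrix(g, dim(a)[1], dim(a)[2]))
}

#' Resample a gray image to the registration input grid
#'
#' Anti-aliased (exact box-overlap area-weighted) resampling when shrinking,
#' bilinear when enlarging; 256 x 192 by default, the fixed input size of the
#' displacement-field estimator. Aspect ratio is not preserved: images are
#' stretched onto the fixed grid.
#'
#' @param img a [gray_image].
#' @param width,height target size in pixels (default 256 x 192).
#' @return a [gray_image] of size `height` x `width`.
#' @export
resize_input <- function(img, width = 256L, height = 192L) {
  m <- as_gray_matrix(img)
  if (height <= nrow(m) && width <= ncol(m)) {
    out <- cpp_resize_area(m, as.integer(height), as.integer(width))
  } else {
    out <- cpp_resize_bilinear(m, as.integer(height), as.integer(width))
  }
  gray_image(out)
}

#' Otsu threshold of a gray image
#'
#' @param img a [gray_image].
#' @param bins histogram bin count (default 256).
#' @return threshold in [0, 1]; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img, bins = 256L) {
  v <- as.vector(as_gray_matrix(img))
  h <- tabulate(pmin(floor(v * bins), bins - 1) + 1L, nbins = bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(bins) - 0.5))
  mu_t <- mu[bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  k / bins
}

#' Foreground mask of a specimen or histology image
#'
#' Thresholds the image (Otsu by default), keeps the largest 4-connected
#' component and fills its holes. This is the binary mask used by the Dice
#' score.
#'
#' @param img a [gray_image].
#' @param threshold optional manual threshold in (0, 1); default Otsu.
#' @return a logical matrix (TRUE = foreground).
#' @export
foreground_mask <- function(img, threshold = NULL) {
  m <- as_gray_matrix(img)
  if (max(m) - min(m) < 1e-9) stopf("foreground_mask: blank image")
  if (is.null(threshold)) threshold <- otsu_threshold(gray_image(m))
  fg <- matrix(as.integer(m > threshold), nrow(m), ncol(m))
  if (sum(fg) == 0L) stopf("foreground_mask: empty foreground at threshold %.3f", threshold)
  lab <- cpp_label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  comp <- lab == keep
  fill_holes(comp)
}

# Fill holes: background components not 4-connected to the image border.
fill_holes <- function(mask) {
  bg <- matrix(as.integer(!mask), nrow(mask), ncol(mask))
  lab <- cpp_label_components(bg)
  border_labels <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ],
                                    lab[, 1], lab[, ncol(lab)])), 0L)
  holes <- lab > 0L & !matrix(lab %in% border_labels, nrow(lab), ncol(lab))
  mask | holes
}
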