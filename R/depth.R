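# Base-plane calibration of a downward-facing depth camera.
#
# The work surface under the camera is never perfectly aligned with the
# sensor, so raw depth frames of a flat table show a residual tilt. We model
# the surface as the plane a*x + b*y + z + c = 0 and fit (a, b, c) by linear
# least squares on the vertical residual; corrected depth is then
# z_new = z + a*x + b*y + c, which is 0 on the base plane and equals object
# height above it elsewhere.
#
# Pixel coordinates are 0-based (x = column, y = row) in pixel units unless
# the caller rescales; the plane model is unit-agnostic in (x, y).

#' Depth frame container
#'
#' A depth frame is a numeric matrix of depth values in millimetres together
#' with a logical validity mask (real sensors emit dropouts). Values must be
#' finite wherever the mask is `TRUE`.
#'
#' @param values numeric matrix of depth values (mm), rows x cols.
#' @param valid_mask optional logical matrix of the same dimensions; defaults
#'   to pixels with finite values inside `z_range`.
#' @param z_range optional numeric length-2 vector `[z_min, z_max]` (mm)
#'   gating validity when `valid_mask` is not given. Default: no gate.
#' @return an object of class `depth_frame` with elements `values` and
#'   `valid_mask`.
#' @export
depth_frame <- function(values, valid_mask = NULL, z_range = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("depth_frame: 'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stopf("depth_frame: dimensions must be positive")
  if (is.null(valid_mask)) {
    valid_mask <- is.finite(values)
    if (!is.null(z_range)) {
      valid_mask <- valid_mask & values >= z_range[1] & values <= z_range[2]
    }
  }
  if (!is.logical(valid_mask) || !all(dim(valid_mask) == dim(values)))
    stopf("depth_frame: 'valid_mask' must be a logical matrix matching 'values'")
  if (any(!is.finite(values[valid_mask])))
    stopf("depth_frame: non-finite depth at pixels marked valid")
  structure(list(values = values, valid_mask = valid_mask),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame %d x %d, %d valid px, depth range [%.2f, %.2f] mm>\n",
              nrow(x$values), ncol(x$values), sum(x$valid_mask),
              suppressWarnings(min(x$values[x$valid_mask])),
              suppressWarnings(max(x$values[x$valid_mask]))))
  invisible(x)
}

#' Average a stack of depth frames
#'
#' Per-pixel mean over the stack to suppress sensor noise before plane
#' fitting; a pixel stays valid only if it is valid in every frame.
#'
#' @param frames list of [depth_frame] objects with identical dimensions.
#' @return a single [depth_frame].
#' @export
average_depth_frames <- function(frames) {
  if (length(frames) < 1L) stopf("average_depth_frames: need at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "depth_frame")))
    stopf("average_depth_frames: all elements must be depth_frame objects")
  d <- dim(frames[[1]]$values)
  for (f in frames)
    if (!all(dim(f$values) == d))
      stopf("average_depth_frames: frames have mismatched dimensions")
  acc <- matrix(0, d[1], d[2])
  mask <- matrix(TRUE, d[1], d[2])
  for (f in frames) {
    vals <- f$values
    vals[!f$valid_mask] <- 0      # excluded below via the mask conjunction
    acc <- acc + vals
    mask <- mask & f$valid_mask
  }
  avg <- acc / length(frames)
  avg[!mask] <- NA_real_
  depth_frame(avg, valid_mask = mask)
}

#' Base-plane model
#'
#' Parameters of the plane a*x + b*y + z + c = 0: dimensionless slopes `a`
#' (per pixel in x), `b` (per pixel in y) and offset `c` in millimetres.
#'
#' @param a,b,c finite numeric scalars.
#' @return an object of class `plane_model`.
#' @export
plane_model <- function(a, b, c) {
  p <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c))
  if (!all(is.finite(p))) stopf("plane_model: parameters must be finite")
  structure(as.list(p), class = "plane_model")
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("<plane_model a=%.6g b=%.6g c=%.6g>  (a*x + b*y + z + c = 0)\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Fit the base plane to a depth frame
#'
#' Randomly samples valid pixels (seeded) and minimizes the mean squared
#' vertical residual (1/n) * sum (a*x_i + b*y_i + z_i + c)^2. The objective
#' is linear in (a, b, c), so the closed-form normal-equations solution is
#' exact; no iterative solver is involved.
#'
#' @param depth a [depth_frame].
#' @param n_samples number of sample points (default 10000); all valid pixels
#'   are used when fewer are available.
#' @param seed integer seed for the point sampling.
#' @return a [plane_model].
#' @export
fit_base_plane <- function(depth, n_samples = 10000L, seed = 0L) {
  if (!inherits(depth, "depth_frame")) stopf("fit_base_plane: need a depth_frame")
  idx <- which(depth$valid_mask)
  if (length(idx) < 3L) stopf("fit_base_plane: fewer than 3 valid pixels")
  if (length(idx) > n_samples) {
    idx <- with_seed(seed, sample(idx, n_samples))
  }
  H <- nrow(depth$values)
  y <- (idx - 1L) %% H            # 0-based row
  x <- (idx - 1L) %/% H           # 0-based column
  z <- depth$values[idx]
  fit_plane_points(x, y, z)
}

# Closed-form normal-equations solve for min (1/n) sum (a x + b y + z + c)^2.
fit_plane_points <- function(x, y, z) {
  M <- cbind(x = x, y = y, const = 1)
  XtX <- crossprod(M)
  if (rcond_sym(XtX) < 1e-12)
    stopf("fit_base_plane: degenerate geometry (collinear sample points)")
  theta <- solve(XtX, -crossprod(M, z))
  plane_model(theta[1], theta[2], theta[3])
}

rcond_sym <- function(A) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Mean squared plane residual
#'
#' The fitted objective (1/n) * sum (a*x + b*y + z + c)^2 evaluated over the
#' valid pixels of a frame; useful for comparing candidate planes.
#'
#' @param depth a [depth_frame].
#' @param plane a [plane_model].
#' @return mean squared residual in mm^2.
#' @export
plane_residual <- function(depth, plane) {
  idx <- which(depth$valid_mask)
  H <- nrow(depth$values)
  y <- (idx - 1L) %% H
  x <- (idx - 1L) %/% H
  r <- plane$a * x + plane$b * y + depth$values[idx] + plane$c
  mean(r^2)
}

#' Correct a depth frame for base-plane inclination
#'
#' Applies z_new = z + a*x + b*y + c pixelwise; on the base plane the result
#' is 0 and an object of height h above it maps to h. The validity mask is
#' unchanged.
#'
#' @param depth a [depth_frame].
#' @param plane a [plane_model].
#' @return a corrected [depth_frame].
#' @export
correct_depth <- function(depth, plane) {
  if (!inherits(depth, "depth_frame")) stopf("correct_depth: need a depth_frame")
  if (!inherits(plane, "plane_model")) stopf("correct_depth: need a plane_model")
  H <- nrow(depth$values); W <- ncol(depth$values)
  x <- matrix(rep(0:(W - 1L), each = H), H, W)
  y <- matrix(rep(0:(H - 1L), times = W), H, W)
  vals <- depth$values + plane$a * x + plane$b * y + plane$c
  vals[!depth$valid_mask] <- NA_real_
  depth_frame(vals, valid_mask = depth$valid_mask)
}
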