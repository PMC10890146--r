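# Deformable registration of the moving specimen image to the fixed
# histology image.
#
# The estimator produces a dense displacement field (DDF) phi on the moving
# image's grid, using the backward convention: the registered image is
# M(phi)(x, y) = M(x + u(x,y), y + v(x,y)), sampled bilinearly with boundary
# clamping. Alignment quality is scored by mutual information (shared
# information between the two intensity histograms, robust across
# modalities) and by the Dice overlap of foreground masks.
#
# Instead of an amortized network, the field is fitted per image pair by
# maximizing MI(F, M(phi)) - lambda * smoothness, with a coarse-to-fine
# pyramid of bilinearly upsampled control-point grids and monotone greedy
# coordinate ascent (step halving). This meets the same contract
# deterministically and needs no trained weights.

#' Mutual information between two gray images, in bits
#'
#' MI = sum_ij p(i,j) log2( p(i,j) / (p(i) p(j)) ) over a hard-binned joint
#' intensity histogram on [0, 1]. Zero for independent images; equals the
#' (binned) entropy H(a) when b = a.
#'
#' @param a,b [gray_image]s (or matrices in [0, 1]) of equal dimensions.
#' @param bins histogram bin count (>= 2; default 32).
#' @return mutual information in bits (non-negative).
#' @export
mutual_information <- function(a, b, bins = 32L) {
  a <- as_gray_matrix(a); b <- as_gray_matrix(b)
  if (!all(dim(a) == dim(b))) stopf("mutual_information: dimension mismatch")
  if (bins < 2L) stopf("mutual_information: need bins >= 2")
  cpp_mi_bits(a, b, as.integer(bins))
}

#' Shannon entropy of a gray image's binned histogram, in bits
#' @inheritParams mutual_information
#' @param img a [gray_image].
#' @return entropy in bits.
#' @export
image_entropy <- function(img, bins = 32L) {
  mutual_information(img, img, bins = bins)
}

#' Dice overlap of two binary masks
#'
#' 2 |A intersect B| / (|A| + |B|); 1 when both masks are empty.
#'
#' @param a,b logical (or 0/1) matrices of equal dimensions.
#' @return Dice score in [0, 1].
#' @export
dice_score <- function(a, b) {
  a <- a != 0; b <- b != 0
  if (!all(dim(a) == dim(b))) stopf("dice_score: dimension mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' Displacement field constructor
#'
#' Per-pixel displacements in pixels: `u` along x (columns), `v` along y
#' (rows), both the size of the moving image. Backward convention (see
#' [warp]).
#'
#' @param u,v numeric matrices of identical dimensions, finite.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(u, v) {
  if (!is.matrix(u) || !is.matrix(v) || !all(dim(u) == dim(v)))
    stopf("displacement_field: u and v must be matrices of equal size")
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stopf("displacement_field: non-finite displacements")
  structure(list(u = u, v = v), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("<displacement_field %d x %d, |d| mean %.2f max %.2f px>\n",
              nrow(x$u), ncol(x$u), mean(mag), max(mag)))
  invisible(x)
}

#' Warp a gray image with a displacement field
#'
#' Backward bilinear resampling: output(x, y) = moving(x + u, y + v), with
#' out-of-bounds samples clamped to the boundary value.
#'
#' @param moving a [gray_image].
#' @param field a [displacement_field] of matching dimensions.
#' @return the warped [gray_image].
#' @export
warp <- function(moving, field) {
  m <- as_gray_matrix(moving)
  if (!inherits(field, "displacement_field")) stopf("warp: need a displacement_field")
  if (!all(dim(m) == dim(field$u))) stopf("warp: field dimensions do not match image")
  gray_image(cpp_warp_bilinear(m, field$u, field$v))
}

#' Registration configuration
#'
#' @param bins MI histogram bins (default 32).
#' @param lambda weight of the squared-gradient (diffusion) smoothness
#'   penalty on the dense field, in bits per px^2/px^2 (default 0.05).
#' @param levels pyramid levels (default 3: quarter, half, full resolution).
#' @param spacing control-point spacing at full resolution, px (default 16).
#' @param max_sweeps cap on improvement sweeps per step size (default 10).
#' @param seed seed for any stochastic elements (the default optimizer is
#'   deterministic; kept for interface stability).
#' @param width,height enforced input size (default 256 x 192).
#' @return a list of class `reg_config`.
#' @export
reg_config <- function(bins = 32L, lambda = 0.05, levels = 3L, spacing = 16L,
                       max_sweeps = 10L, seed = 0L,
                       width = 256L, height = 192L) {
  stopifnot(bins >= 2L, lambda >= 0, levels >= 1L, spacing >= 2L, max_sweeps >= 1L)
  structure(list(bins = as.integer(bins), lambda = lambda,
                 levels = as.integer(levels), spacing = as.integer(spacing),
                 max_sweeps = as.integer(max_sweeps), seed = as.integer(seed),
                 width = as.integer(width), height = as.integer(height)),
            class = "reg_config")
}

grid_dims <- function(H, W, spacing) {
  c(max(2L, as.integer(round((H - 1) / spacing)) + 1L),
    max(2L, as.integer(round((W - 1) / spacing)) + 1L))
}

#' Estimate a dense displacement field by mutual-information maximization
#'
#' Fits the DDF registering `moving` to `fixed` by maximizing
#' MI(fixed, warp(moving, phi)) - lambda * mean squared gradient of phi.
#' Optimization is coarse-to-fine over a 3-level image pyramid; at each
#' level a control-point grid (spacing 16 px at that level) is refined by
#' greedy coordinate ascent with step halving, so the regularized objective
#' never decreases. The accepted-objective trace is returned for
#' monotonicity checks.
#'
#' @param fixed the fixed [gray_image] (histology, by convention).
#' @param moving the moving [gray_image] (specimen snapshot); both must be
#'   exactly `config$height` x `config$width` (256 x 192 by default).
#' @param config a [reg_config].
#' @return an object of class `registration_result`: `field`
#'   (full-resolution [displacement_field]), `warped` (M(phi)), `mi_before`,
#'   `mi_after` (bits), `dice_before`, `dice_after` (foreground-mask Dice),
#'   `objective_trace`, `converged`.
#' @export
estimate_ddf <- function(fixed, moving, config = reg_config()) {
  Fm <- as_gray_matrix(fixed); Mm <- as_gray_matrix(moving)
  if (nrow(Fm) != config$height || ncol(Fm) != config$width ||
      nrow(Mm) != config$height || ncol(Mm) != config$width)
    stopf("estimate_ddf: images must be %d x %d (width x height); resize first",
          config$width, config$height)
  scales <- rev(2^(seq_len(config$levels) - 1L))   # e.g. 4, 2, 1
  gu <- gv <- NULL
  trace <- numeric(0)
  converged <- TRUE
  for (s in scales) {
    H <- config$height %/% s; W <- config$width %/% s
    Fs <- cpp_resize_area(Fm, H, W)
    Ms <- cpp_resize_area(Mm, H, W)
    gd <- grid_dims(H, W, config$spacing)
    if (is.null(gu)) {
      gu <- matrix(0, gd[1], gd[2]); gv <- matrix(0, gd[1], gd[2])
    } else {
      # upsample the coarser grid (align-corners) and double displacements
      gu <- 2 * cpp_grid_to_dense(gu, gd[1], gd[2])
      gv <- 2 * cpp_grid_to_dense(gv, gd[1], gd[2])
    }
    steps <- if (s == max(scales)) c(4, 2, 1, 0.5) else c(2, 1, 0.5)
    res <- cpp_optimize_level(Fs, Ms, gu, gv, config$bins, config$lambda,
                              steps, config$max_sweeps)
    gu <- res$gu; gv <- res$gv
    trace <- c(trace, res$trace)
    if (s == 1L) converged <- !res$hit_cap
  }
  if (!converged)
    warning("estimate_ddf: sweep cap reached while still improving; returning best-so-far field")
  u <- cpp_grid_to_dense(gu, config$height, config$width)
  v <- cpp_grid_to_dense(gv, config$height, config$width)
  field <- displacement_field(u, v)
  warped <- warp(gray_image(Mm), field)
  mi_before <- mutual_information(Fm, Mm, config$bins)
  mi_after <- mutual_information(Fm, warped, config$bins)
  mask_f <- foreground_mask(gray_image(Fm))
  dice_before <- dice_score(mask_f, foreground_mask(gray_image(Mm)))
  dice_after <- dice_score(mask_f, foreground_mask(warped))
  structure(list(field = field, warped = warped,
                 mi_before = mi_before, mi_after = mi_after,
                 dice_before = dice_before, dice_after = dice_after,
                 objective_trace = trace, converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("<registration_result: MI %.3f -> %.3f bits, ",
                     "Dice %.3f -> %.3f%s>\n"),
              x$mi_before, x$mi_after, x$dice_before, x$dice_after,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
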