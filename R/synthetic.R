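# Deterministic synthetic phantoms.
#
# No study data ships with the package, so every stage is exercised on
# generated scenes with recorded ground truth: inclined noisy depth planes
# (optionally with a raised box), checkerboard point pairs under a known
# rigid transform, and specimen/histology image pairs related by a known
# smooth deformation, with class-annotated regions and projected POI dots.
# Identical specs give bit-identical outputs; truth is always returned with
# the data so tests never re-derive it from images.

#' Phantom specification
#'
#' One object fixing every free parameter of the generators; the seed fixes
#' all randomness.
#'
#' @param seed integer seed.
#' @param dims c(height, width) of specimen/histology images (default
#'   192 x 256, the registration input grid).
#' @param depth_dims c(height, width) of depth frames (default 120 x 160).
#' @param plane true base-plane parameters c(a, b, c); default
#'   c(0.05, -0.03, -500): a gently inclined surface about 500 mm from the
#'   sensor.
#' @param depth_noise_sd depth sensor noise SD in mm (default 0.5).
#' @param box_height height of the optional raised box in mm (default 10;
#'   used only when a scene is generated with `with_box = TRUE`).
#' @param rotation_deg,rotation_axis,translation true camera-to-projector
#'   transform: default 30 degrees about z with T = (10, 5, 2) mm.
#' @param deform_amplitude maximum displacement of the true deformation in
#'   px (default 8, the magnitude of gross-sectioning distortion at the
#'   256 x 192 working scale).
#' @param deform_scale smoothness scale of the deformation in px (default
#'   32; Gaussian SD is scale/2 and the field is tapered to zero within
#'   `scale` px of the border).
#' @param n_pois number of projected measurement points (default 5).
#' @param poi_radius probe radius in px (default 5).
#' @param dot_radius projected dot radius in px (default 3).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 0L, dims = c(192L, 256L),
                         depth_dims = c(120L, 160L),
                         plane = c(a = 0.05, b = -0.03, c = -500),
                         depth_noise_sd = 0.5, box_height = 10,
                         rotation_deg = 30, rotation_axis = c(0, 0, 1),
                         translation = c(10, 5, 2),
                         deform_amplitude = 8, deform_scale = 32,
                         n_pois = 5L, poi_radius = 5, dot_radius = 3) {
  stopifnot(deform_amplitude >= 0, deform_scale > 0, n_pois >= 1L)
  structure(list(seed = as.integer(seed), dims = as.integer(dims),
                 depth_dims = as.integer(depth_dims), plane = plane,
                 depth_noise_sd = depth_noise_sd, box_height = box_height,
                 rotation_deg = rotation_deg, rotation_axis = rotation_axis,
                 translation = translation,
                 deform_amplitude = deform_amplitude,
                 deform_scale = deform_scale, n_pois = as.integer(n_pois),
                 poi_radius = poi_radius, dot_radius = dot_radius),
            class = "phantom_spec")
}

true_transform <- function(spec) {
  ax <- spec$rotation_axis / sqrt(sum(spec$rotation_axis^2))
  rigid_transform(axisangle_to_rot(ax * spec$rotation_deg * pi / 180),
                  spec$translation)
}

#' Generate a depth-camera scene of the inclined base plane
#'
#' Frames follow the plane a*x + b*y + z + c = 0 (z is the camera-space
#' height coordinate, so a raised object increases z) plus i.i.d. Gaussian
#' sensor noise; optionally a raised box occupies the central quarter of the
#' frame.
#'
#' @param spec a [phantom_spec].
#' @param n_frames number of frames to capture (>= 1).
#' @param with_box include the raised box of height `spec$box_height` mm.
#' @return list with `frames` (list of [depth_frame]), and `truth`
#'   (the true [plane_model] and the logical box mask).
#' @export
generate_depth_scene <- function(spec, n_frames = 50L, with_box = FALSE) {
  H <- spec$depth_dims[1]; W <- spec$depth_dims[2]
  a <- spec$plane[1]; b <- spec$plane[2]; cc <- spec$plane[3]
  x <- matrix(rep(0:(W - 1L), each = H), H, W)
  y <- matrix(rep(0:(H - 1L), times = W), H, W)
  base <- -(a * x + b * y + cc)
  box <- matrix(FALSE, H, W)
  if (with_box) {
    box[(H %/% 4):(H %/% 2), (W %/% 4):(W %/% 2)] <- TRUE
    base <- base + spec$box_height * box
  }
  frames <- with_seed(spec$seed, {
    lapply(seq_len(n_frames), function(i) {
      noise <- if (spec$depth_noise_sd > 0)
        matrix(rnorm(H * W, sd = spec$depth_noise_sd), H, W) else 0
      depth_frame(base + noise)
    })
  })
  list(frames = frames,
       truth = list(plane = plane_model(a, b, cc), box_mask = box))
}

#' Generate checkerboard calibration point pairs
#'
#' Emulates projecting a 4 x 5 checkerboard (12 inner corners) at several
#' heights and orientations: each configuration places a planar 3 x 4 corner
#' grid (20 mm pitch) at a random pose, maps it by the true rigid transform,
#' and adds isotropic Gaussian noise to the projector-side points.
#'
#' @param spec a [phantom_spec].
#' @param n_configs number of board configurations (12 pairs each).
#' @param noise_sd projector-point noise SD in mm (default 0).
#' @return list with `pairs` (data.frame, see [point_pairs]) and `truth`
#'   (the true [rigid_transform]).
#' @export
generate_calibration_pairs <- function(spec, n_configs = 5L, noise_sd = 0) {
  if (n_configs < 1L) stopf("generate_calibration_pairs: n_configs >= 1")
  tt <- true_transform(spec)
  pitch <- 20
  corners <- as.matrix(expand.grid(x = 0:3 * pitch, y = 0:2 * pitch))
  corners <- cbind(corners, z = 0)
  cam <- with_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(n_configs), function(i) {
      ang <- runif(1, 0, 2 * pi)
      tilt <- axisangle_to_rot(c(runif(2, -0.15, 0.15), ang))
      off <- c(runif(2, -60, 60), runif(1, 0, 100))
      sweep(corners %*% t(tilt), 2, off, "+")
    }))
  })
  proj <- apply_transform(tt, cam)
  if (noise_sd > 0) {
    proj <- proj + with_seed(spec$seed + 1L,
      matrix(rnorm(length(proj), sd = noise_sd), nrow(proj), 3))
  }
  list(pairs = point_pairs(cam, proj), truth = list(transform = tt))
}

#' Generate a smooth random displacement field
#'
#' Seeded white noise smoothed with a Gaussian (SD = scale/2), tapered to
#' zero within `scale` px of the image border (so the foreground stays in
#' frame), then rescaled so the maximum displacement magnitude equals
#' `amplitude` exactly (zero field when amplitude = 0).
#'
#' @param spec a [phantom_spec].
#' @param shape c(height, width); defaults to `spec$dims`.
#' @param amplitude,scale override `spec$deform_amplitude` / `deform_scale`.
#' @return a [displacement_field].
#' @export
generate_smooth_deformation <- function(spec, shape = spec$dims,
                                        amplitude = spec$deform_amplitude,
                                        scale = spec$deform_scale) {
  H <- shape[1]; W <- shape[2]
  if (amplitude == 0)
    return(displacement_field(matrix(0, H, W), matrix(0, H, W)))
  raw <- with_seed(spec$seed, list(u = matrix(rnorm(H * W), H, W),
                                   v = matrix(rnorm(H * W), H, W)))
  u <- cpp_gaussian_blur(raw$u, scale / 2)
  v <- cpp_gaussian_blur(raw$v, scale / 2)
  dy <- pmin(0:(H - 1L), (H - 1L):0)
  dx <- pmin(0:(W - 1L), (W - 1L):0)
  sm <- function(t) t * t * (3 - 2 * t)           # smoothstep
  wy <- sm(pmin(1, dy / scale)); wx <- sm(pmin(1, dx / scale))
  w <- outer(wy, wx)
  u <- u * w; v <- v * w
  m <- max(sqrt(u^2 + v^2))
  if (m > 0) { u <- u * amplitude / m; v <- v * amplitude / m }
  displacement_field(u, v)
}

# Class layout of the specimen phantom in specimen space: 0 background,
# 1 fat analog (outer ellipse), 2 connective analog (inner ellipse),
# 3 tumor analog (blob inside the connective region).
phantom_class_map <- function(H, W) {
  x <- matrix(rep(0:(W - 1L), each = H), H, W)
  y <- matrix(rep(0:(H - 1L), times = W), H, W)
  cxs <- (W - 1) / 2; cys <- (H - 1) / 2
  cls <- matrix(0L, H, W)
  inside <- function(cx, cy, rx, ry)
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
  cls[inside(cxs, cys, 0.34 * W, 0.32 * H)] <- 1L
  cls[inside(cxs + 0.023 * W, cys + 0.01 * H, 0.23 * W, 0.21 * H)] <- 2L
  cls[inside(cxs + 0.08 * W, cys - 0.05 * H, 0.10 * W, 0.10 * H)] <- 3L
  cls
}

# RGB colors per class, chosen so the saturation channel separates classes
# (bg 0, tumor ~0.17, connective ~0.42, fat 0.60).
phantom_palette <- function() {
  rbind(background = c(0.05, 0.05, 0.05),
        fat        = c(1.00, 0.85, 0.40),
        connective = c(0.95, 0.55, 0.65),
        tumor      = c(0.72, 0.60, 0.72))
}

# Histology grayscale intensity per class.
phantom_histology_levels <- function() c(0.05, 0.85, 0.55, 0.30)

phantom_legend <- function() c("0" = "background", "1" = "fat",
                               "2" = "connective", "3" = "tumor")

# Invert the backward map x + psi(x) = target by fixed-point iteration.
invert_field_at <- function(field, target, iters = 30L) {
  H <- nrow(field$u); W <- ncol(field$u)
  x <- target[1]; y <- target[2]
  for (i in seq_len(iters)) {
    ux <- sample_field(field$u, y, x, H, W)
    vy <- sample_field(field$v, y, x, H, W)
    x <- target[1] - ux; y <- target[2] - vy
  }
  c(x, y)
}

sample_field <- function(m, y, x, H, W) bilinear_at(m, y, x)

bilinear_at <- function(m, y, x) {
  H <- nrow(m); W <- ncol(m)
  x <- min(max(x, 0), W - 1); y <- min(max(y, 0), H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, W - 1); y1 <- min(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  m[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) + m[y0 + 1, x1 + 1] * fx * (1 - fy) +
    m[y1 + 1, x0 + 1] * (1 - fx) * fy + m[y1 + 1, x1 + 1] * fx * fy
}

#' Generate a specimen/histology phantom pair with ground truth
#'
#' Produces the four images of one validation case: the specimen snapshot
#' S_O (colored elliptical phantom with fat/connective/tumor-analog
#' regions on a dark background), S_POI (S_O plus bright projected dots at
#' recorded centers), the grayscale histology image H_O (the class layout
#' rendered at histology intensities, deformed by the true smooth field),
#' and the annotated class raster in histology space. The truth element
#' carries the deformation field (the field the registration should
#' recover), POI centers in both spaces, the intended per-POI label
#' percentages (computed analytically from the class raster, not via the
#' pipeline), and the true foreground mask.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `s_o`, `s_poi` ([rgb_image]), `h_o`
#'   ([gray_image]), `annotation` ([annotation_map]) and `truth`.
#' @export
generate_specimen_pair <- function(spec) {
  H <- spec$dims[1]; W <- spec$dims[2]
  cls <- phantom_class_map(H, W)
  pal <- phantom_palette()
  field <- generate_smooth_deformation(spec)
  # histology-space class raster: A(x) = class(x + psi(x)), nearest sampling
  cls_hist <- cpp_warp_nearest(cls, field$u, field$v)

  noise <- with_seed(spec$seed + 2L, list(
    rgb = array(rnorm(H * W * 3, sd = 0.01), c(H, W, 3)),
    hist = matrix(rnorm(H * W, sd = 0.02), H, W)))

  px <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    chan <- matrix(pal[cls + 1L, ch], H, W) + noise$rgb[, , ch]
    px[, , ch] <- pmin(pmax(chan, 0), 1)
  }
  s_o <- rgb_image(px)

  lev <- phantom_histology_levels()
  h <- matrix(lev[cls_hist + 1L], H, W)
  h <- cpp_gaussian_blur(h, 0.7) + noise$hist
  h_o <- gray_image(pmin(pmax(h, 0), 1))

  centers <- phantom_poi_centers(spec, cls)
  s_poi_px <- px
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]; r <- spec$dot_radius
    for (x in floor(cx - r):ceiling(cx + r))
      for (y in floor(cy - r):ceiling(cy + r))
        if ((x - cx)^2 + (y - cy)^2 <= r^2)
          s_poi_px[y + 1L, x + 1L, ] <- 1
  }
  s_poi <- rgb_image(s_poi_px)

  mapped <- t(apply(centers, 1, function(p) invert_field_at(field, p)))
  colnames(mapped) <- c("x", "y")

  intended <- poi_percentages(centers, spec$poi_radius, cls, phantom_legend())

  list(s_o = s_o, s_poi = s_poi, h_o = h_o,
       annotation = annotation_map(cls_hist, phantom_legend()),
       truth = list(field = field, centers = centers,
                    mapped_centers = mapped, intended_labels = intended,
                    foreground = cls > 0L))
}

# Deterministic POI anchors (one in each tissue analog) with seeded jitter.
phantom_poi_centers <- function(spec, cls) {
  H <- nrow(cls); W <- ncol(cls)
  anchors <- rbind(c(0.58, 0.45),   # tumor analog
                   c(0.43, 0.50),   # connective analog
                   c(0.23, 0.50), c(0.77, 0.57), c(0.50, 0.21),  # fat
                   c(0.50, 0.72), c(0.32, 0.34), c(0.66, 0.66))
  n <- min(spec$n_pois, nrow(anchors))
  pts <- cbind(anchors[seq_len(n), 1] * (W - 1), anchors[seq_len(n), 2] * (H - 1))
  jit <- with_seed(spec$seed + 3L, matrix(runif(2 * n, -2, 2), n, 2))
  pts <- round(pts + jit)
  colnames(pts) <- c("x", "y")
  pts
}

# Analytic per-POI class percentages by direct pixel counting on a class
# raster (pixel-center-inside-circle rule), independent of label_extraction.
poi_percentages <- function(centers, radius, cls, legend) {
  rows <- list()
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    xs <- floor(cx - radius):ceiling(cx + radius)
    ys <- floor(cy - radius):ceiling(cy + radius)
    labs <- integer(0)
    for (x in xs) for (y in ys)
      if ((x - cx)^2 + (y - cy)^2 <= radius^2)
        labs <- c(labs, cls[y + 1L, x + 1L])
    for (code in names(legend))
      rows[[length(rows) + 1L]] <- data.frame(
        poi_id = k, class = unname(legend[code]),
        percent = 100 * sum(labs == as.integer(code)) / length(labs),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
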