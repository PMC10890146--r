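# Plain-text file interchange.
#
# This toolchain runs in environments without binary image libraries, so all
# rasters use ASCII formats: gray images as PGM (P2), RGB images as PPM
# (P3), depth frames as PGM with value = depth in 0.1 mm steps (maxval
# 65535), displacement fields as a two-plane text format with a small
# header, and models (plane, rigid transform, metrics) as JSON.

#' Write a gray or RGB image as ASCII PNM
#'
#' Gray images become P2 (PGM), RGB images P3 (PPM), maxval 255.
#'
#' @param img a [gray_image] or [rgb_image].
#' @param path output file path.
#' @export
write_pnm <- function(img, path) {
  if (inherits(img, "rgb_image")) {
    a <- round(unclass(img) * 255)
    H <- dim(a)[1]; W <- dim(a)[2]
    # interleave channels row-major: R G B per pixel
    flat <- integer(H * W * 3)
    idx <- 1L
    vals <- aperm(a, c(3, 2, 1))   # channel, col, row
    flat <- as.integer(as.vector(vals))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", sprintf("%d %d", W, H), "255"), con)
    writeLines(paste(flat, collapse = " "), con)
  } else {
    m <- round(as_gray_matrix(img) * 255)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
    writeLines(apply(m, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read an ASCII PNM image
#'
#' @param path a P2 (PGM) or P3 (PPM) file.
#' @return a [gray_image] (P2) or [rgb_image] (P3), intensities in [0, 1].
#' @export
read_pnm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1]
  W <- as.integer(toks[2]); H <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)]) / maxval
  if (magic == "P2") {
    gray_image(matrix(vals, H, W, byrow = TRUE))
  } else if (magic == "P3") {
    a <- array(0, c(H, W, 3))
    m <- matrix(vals, ncol = 3, byrow = TRUE)   # one row per pixel
    for (ch in 1:3) a[, , ch] <- matrix(m[, ch], H, W, byrow = TRUE)
    rgb_image(a)
  } else stopf("read_pnm: unsupported magic '%s'", magic)
}

#' Write a depth frame as 16-bit ASCII PGM (0.1 mm steps)
#'
#' Values are stored as round(depth * 10) clamped to [0, 65535]; invalid
#' pixels are stored as 0 and restored as invalid on read.
#'
#' @param depth a [depth_frame].
#' @param path output path.
#' @export
write_depth_pgm <- function(depth, path) {
  m <- depth$values * 10
  m[!depth$valid_mask] <- 0
  m <- pmin(pmax(round(m), 0), 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "65535"), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a depth frame written by [write_depth_pgm]
#' @param path input path.
#' @return a [depth_frame] in mm; zero-valued pixels are marked invalid.
#' @export
read_depth_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  W <- as.integer(toks[2]); H <- as.integer(toks[3])
  vals <- matrix(as.numeric(toks[-(1:4)]), H, W, byrow = TRUE) / 10
  depth_frame(vals, valid_mask = vals > 0)
}

#' Serialize a plane model to JSON
#' @param plane a [plane_model]. @param path output path.
#' @export
write_plane_json <- function(plane, path) {
  jsonlite::write_json(list(a = plane$a, b = plane$b, c = plane$c), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plane model from JSON
#' @param path input path.
#' @return a [plane_model].
#' @export
read_plane_json <- function(path) {
  j <- jsonlite::read_json(path)
  plane_model(j$a, j$b, j$c)
}

#' Serialize a rigid transform to JSON (R row-major, T)
#' @param t a [rigid_transform]. @param path output path.
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(list(R = as.vector(t(t$R)), T = t$T), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path input path.
#' @return a [rigid_transform].
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(j$R, 3, 3, byrow = TRUE), j$T)
}

#' Write a displacement field as text
#'
#' Format: a header line `ppm-ddf <H> <W>` followed by H lines of u (x
#' displacements) and H lines of v (y displacements), whitespace-separated,
#' full double precision. The backward-warp convention is part of the
#' format contract.
#'
#' @param field a [displacement_field]. @param path output path.
#' @export
write_ddf <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  H <- nrow(field$u); W <- ncol(field$u)
  writeLines(sprintf("ppm-ddf %d %d", H, W), con)
  fmt <- function(m) apply(m, 1, function(r) paste(formatC(r, digits = 17, format = "g"),
                                                   collapse = " "))
  writeLines(fmt(field$u), con)
  writeLines(fmt(field$v), con)
  invisible(path)
}

#' Read a displacement field written by [write_ddf]
#' @param path input path.
#' @return a [displacement_field].
#' @export
read_ddf <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "ppm-ddf") stopf("read_ddf: not a ppm-ddf file")
  H <- as.integer(hdr[2]); W <- as.integer(hdr[3])
  nums <- function(ls) do.call(rbind, lapply(ls, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  u <- nums(lines[2:(H + 1)])
  v <- nums(lines[(H + 2):(2 * H + 1)])
  displacement_field(u, v)
}

#' Write point pairs as CSV (columns xc, yc, zc, xp, yp, zp)
#' @param pairs point-pair data.frame. @param path output path.
#' @export
write_pairs_csv <- function(pairs, path) {
  write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' Read point pairs from CSV
#' @param path input path.
#' @return a point-pair data.frame.
#' @export
read_pairs_csv <- function(path) {
  p <- read.csv(path)
  pairs_matrices(p)  # validates columns
  p
}

#' Write an annotation map as an ASCII PGM of class codes plus JSON legend
#' @param ann an [annotation_map]. @param path raster path; the legend is
#'   written next to it as `<path>.legend.json`.
#' @export
write_annotation <- function(ann, path) {
  m <- ann$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  jsonlite::write_json(as.list(ann$legend), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an annotation map written by [write_annotation]
#' @param path raster path (legend expected at `<path>.legend.json`).
#' @return an [annotation_map].
#' @export
read_annotation <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  W <- as.integer(toks[2]); H <- as.integer(toks[3])
  m <- matrix(as.integer(toks[-(1:4)]), H, W, byrow = TRUE)
  legend <- unlist(jsonlite::read_json(paste0(path, ".legend.json"),
                                       simplifyVector = TRUE))
  annotation_map(m, legend)
}
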