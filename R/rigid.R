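# Camera-to-projector calibration: estimate the rigid transform
# [R T; 0 1] mapping camera-space points to projector-space points from 3D
# point pairs (checkerboard corners projected at several heights), and report
# the calibration RMSE.

#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1 to 1e-8).
#' @param T length-3 translation vector in mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(R, T) {
  R <- matrix(as.numeric(R), 3, 3)
  T <- as.numeric(T)
  if (length(T) != 3L) stopf("rigid_transform: T must have length 3")
  if (!all(is.finite(R)) || !all(is.finite(T)))
    stopf("rigid_transform: non-finite parameters")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stopf("rigid_transform: R is not orthonormal (R'R != I)")
  if (abs(det(R) - 1) > 1e-8)
    stopf("rigid_transform: det(R) != +1 (improper rotation)")
  structure(list(R = R, T = T), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$R)
  cat(sprintf("<rigid_transform: rotation %.3f deg, |T| = %.3f mm>\n",
              ang, sqrt(sum(x$T^2))))
  invisible(x)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param R 3x3 rotation matrix.
#' @return angle in [0, 180] degrees.
#' @export
rotation_angle_deg <- function(R) {
  ctheta <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ctheta))) * 180 / pi
}

#' Apply a rigid transform to 3D points
#'
#' @param t a [rigid_transform].
#' @param points n x 3 numeric matrix (or length-3 vector) of points in mm.
#' @return n x 3 matrix of transformed points `R p + T`.
#' @export
apply_transform <- function(t, points) {
  if (!inherits(t, "rigid_transform")) stopf("apply_transform: need a rigid_transform")
  p <- as_points3(points)
  sweep(p %*% t(t$R), 2, t$T, "+")
}

as_points3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stopf("points must be n x 3")
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stopf("points must be finite")
  points
}

#' Point-pair table constructor
#'
#' Calibration point pairs: camera-space and projector-space coordinates of
#' the same physical checkerboard corner, in mm.
#'
#' @param camera n x 3 matrix of camera-space points.
#' @param projector n x 3 matrix of projector-space points.
#' @return a data.frame with columns xc, yc, zc, xp, yp, zp.
#' @export
point_pairs <- function(camera, projector) {
  camera <- as_points3(camera); projector <- as_points3(projector)
  if (nrow(camera) != nrow(projector))
    stopf("point_pairs: camera and projector point counts differ")
  data.frame(xc = camera[, 1], yc = camera[, 2], zc = camera[, 3],
             xp = projector[, 1], yp = projector[, 2], zp = projector[, 3])
}

pairs_matrices <- function(pairs) {
  need <- c("xc", "yc", "zc", "xp", "yp", "zp")
  if (!all(need %in% names(pairs)))
    stopf("point pairs need columns %s", paste(need, collapse = ", "))
  list(camera = as.matrix(pairs[, c("xc", "yc", "zc")]),
       projector = as.matrix(pairs[, c("xp", "yp", "zp")]))
}

#' Estimate the camera-to-projector rigid transform
#'
#' Least-squares fit of `R p_c + T = p_p` over point pairs. The default is
#' the closed-form orthogonal Procrustes (Kabsch) solution on centered point
#' sets, which is exact for this objective; `polish = TRUE` additionally runs
#' a derivative-free Nelder-Mead refinement over an axis-angle + translation
#' parameterization starting from the closed form.
#'
#' @param pairs data.frame with columns xc, yc, zc, xp, yp, zp (see
#'   [point_pairs]), at least 3 pairs with non-collinear camera points.
#' @param polish logical; run the derivative-free refinement (default FALSE).
#' @return a [rigid_transform].
#' @export
estimate_transform <- function(pairs, polish = FALSE) {
  pm <- pairs_matrices(pairs)
  P <- pm$camera; Q <- pm$projector
  n <- nrow(P)
  if (n < 3L) stopf("estimate_transform: need at least 3 point pairs")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity check on the camera points
  sv <- svd(Pc)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stopf("estimate_transform: degenerate geometry (collinear camera points)")
  Hm <- crossprod(Pc, Qc)          # 3x3 covariance
  s <- svd(Hm)
  d <- det(s$v %*% t(s$u))
  if (d < 0) {
    # for planar (rank-2) point sets the third singular direction is
    # indeterminate and the sign flip is the standard proper-rotation fix;
    # for full-rank data a negative determinant means the correspondence
    # is genuinely mirrored
    if (s$d[3] > 1e-9 * max(s$d[1], 1))
      stopf("estimate_transform: best fit requires a reflection; rigid model violated")
    V <- s$v; V[, 3] <- -V[, 3]
    R <- V %*% t(s$u)
  } else {
    R <- s$v %*% t(s$u)
  }
  T <- cq - as.numeric(R %*% cp)
  t0 <- rigid_transform(R, T)
  if (!polish) return(t0)
  # Nelder-Mead refinement in axis-angle + translation (derivative-free)
  par0 <- c(rot_to_axisangle(t0$R), t0$T)
  obj <- function(par) {
    Rp <- axisangle_to_rot(par[1:3])
    sum((sweep(P %*% t(Rp), 2, par[4:6], "+") - Q)^2)
  }
  fit <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  rigid_transform(axisangle_to_rot(fit$par[1:3]), fit$par[4:6])
}

#' Calibration root-mean-squared error
#'
#' RMSE between mapped camera points and their projector-space targets:
#' sqrt(mean ||R p_c + T - p_p||^2), in mm.
#'
#' @param t a [rigid_transform].
#' @param pairs point-pair data.frame (>= 1 row).
#' @return RMSE in mm.
#' @export
calibration_rmse <- function(t, pairs) {
  pm <- pairs_matrices(pairs)
  if (nrow(pm$camera) < 1L) stopf("calibration_rmse: no point pairs")
  res <- apply_transform(t, pm$camera) - pm$projector
  sqrt(mean(rowSums(res^2)))
}

# axis-angle (rotation vector) <-> rotation matrix
axisangle_to_rot <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rot_to_axisangle <- function(R) {
  th <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (th < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}
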