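# Independent oracles, deliberately implemented by different routes than the
# package code they check.

# Closed-form plane fit from the explicit 3x3 normal-equation sums
# (the package solves the same linear system via crossprod/solve on the
# design matrix; here every sum is accumulated by hand).
oracle_plane_fit <- function(x, y, z) {
  n <- length(x)
  A <- matrix(c(sum(x * x), sum(x * y), sum(x),
                sum(x * y), sum(y * y), sum(y),
                sum(x),     sum(y),     n), 3, 3, byrow = TRUE)
  b <- -c(sum(x * z), sum(y * z), sum(z))
  th <- solve(A, b)
  list(a = th[1], b = th[2], c = th[3])
}

# Per-parameter standard errors of the plane fit from the normal-equation
# covariance sigma^2 (M'M)^-1.
oracle_plane_se <- function(x, y, sigma) {
  M <- cbind(x, y, 1)
  sqrt(diag(sigma^2 * solve(crossprod(M))))
}

# Horn's absolute-orientation method (unit quaternion from the 4x4 matrix
# eigenproblem) -- a closed form independent of the package's SVD route.
oracle_horn <- function(camera, projector) {
  cp <- colMeans(camera); cq <- colMeans(projector)
  P <- sweep(camera, 2, cp); Q <- sweep(projector, 2, cq)
  S <- crossprod(P, Q)   # S[i,j] = sum P_i Q_j
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
              3, 3, byrow = TRUE)
  list(R = R, T = cq - as.numeric(R %*% cp))
}

# Brute-force mutual information: explicit double loop over the joint table.
oracle_mi_bits <- function(a, b, bins) {
  bi <- function(v) pmin(floor(pmax(pmin(v, 1), 0) * bins), bins - 1)
  ia <- bi(as.vector(a)); ib <- bi(as.vector(b))
  n <- length(ia)
  mi <- 0
  for (i in 0:(bins - 1)) for (j in 0:(bins - 1)) {
    pij <- sum(ia == i & ib == j) / n
    if (pij > 0) {
      pi_ <- sum(ia == i) / n
      pj_ <- sum(ib == j) / n
      mi <- mi + pij * log2(pij / (pi_ * pj_))
    }
  }
  mi
}

# Direct set-arithmetic Dice.
oracle_dice <- function(a, b) {
  A <- which(a != 0); B <- which(b != 0)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ppmap:::axisangle_to_rot(ax * runif(1, 0, pi))
}

# Small smooth test image (blurred seeded noise in [0, 1]).
smooth_test_image <- function(H, W, seed = 1, sigma = 6) {
  set.seed(seed)
  m <- ppmap:::cpp_gaussian_blur(matrix(rnorm(H * W), H, W), sigma)
  m <- (m - min(m)) / (max(m) - min(m))
  gray_image(m)
}
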