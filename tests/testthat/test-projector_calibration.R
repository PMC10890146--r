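test_that("apply_transform: identity, translation, closed-form rotation", {
  id <- rigid_transform(diag(3), c(0, 0, 0))
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform(id, pts), pts)

  tr <- rigid_transform(diag(3), c(10, 5, 2))
  expect_equal(as.numeric(apply_transform(tr, c(0, 0, 0))), c(10, 5, 2))

  th <- 30 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- rigid_transform(Rz, c(0, 0, 0))
  expect_equal(as.numeric(apply_transform(rot, c(1, 0, 0))),
               c(cos(th), sin(th), 0), tolerance = 1e-12)
})

test_that("rigid_transform enforces rotation invariants", {
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "det")
  expect_error(rigid_transform(2 * diag(3), c(0, 0, 0)), "orthonormal")
})

test_that("estimate_transform is exact on noiseless pairs and matches Horn's oracle", {
  # identity recovery
  set.seed(1)
  P <- matrix(runif(36, -50, 50), 12, 3)
  est0 <- estimate_transform(point_pairs(P, P))
  expect_lt(max(abs(est0$R - diag(3))), 1e-9)
  expect_lt(max(abs(est0$T)), 1e-9)

  # 12 random points under a known rigid transform
  th <- 30 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Tv <- c(10, 5, 2)
  Q <- sweep(P %*% t(Rz), 2, Tv, "+")
  pairs <- point_pairs(P, Q)
  est <- estimate_transform(pairs)
  expect_lt(max(abs(est$R - Rz)), 1e-9)
  expect_lt(max(abs(est$T - Tv)), 1e-9)
  expect_lt(calibration_rmse(est, pairs), 1e-9)

  # independent quaternion oracle agrees
  horn <- oracle_horn(P, Q)
  expect_lt(max(abs(est$R - horn$R)), 1e-9)
  expect_lt(max(abs(est$T - horn$T)), 1e-9)

  # derivative-free polish does not degrade the exact solution
  estp <- estimate_transform(pairs, polish = TRUE)
  expect_lt(calibration_rmse(estp, pairs), 1e-6)
})

test_that("estimate_transform under noise: accuracy at 60 pairs (Monte Carlo)", {
  set.seed(42)
  reps <- 30
  ok <- replicate(reps, {
    sp <- phantom_spec(seed = sample.int(1e6, 1))
    cp <- generate_calibration_pairs(sp, n_configs = 5, noise_sd = 0.1)
    est <- estimate_transform(cp$pairs)
    tt <- cp$truth$transform
    ang_err <- rotation_angle_deg(t(est$R) %*% tt$R)
    trans_err <- sqrt(sum((est$T - tt$T)^2))
    horn <- oracle_horn(as.matrix(cp$pairs[, 1:3]), as.matrix(cp$pairs[, 4:6]))
    c(ang_err < 0.5, trans_err < 0.2, max(abs(est$R - horn$R)) < 1e-8)
  })
  expect_true(all(ok))
})

test_that("estimate_transform rejects degenerate and reflective geometry", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(estimate_transform(point_pairs(line, line)), "collinear|degenerate")
  expect_error(estimate_transform(point_pairs(line[1:2, ], line[1:2, ])), "at least 3")
  # mirrored target: best fit would need a reflection
  set.seed(2)
  P <- matrix(rnorm(36), 12, 3)
  M <- P %*% diag(c(1, 1, -1))
  expect_error(estimate_transform(point_pairs(P, M)), "reflection")
})

test_that("calibration_rmse: exact cases and optimality of the estimate", {
  one <- point_pairs(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1))
  expect_equal(calibration_rmse(rigid_transform(diag(3), c(0, 0, 0)), one), 5)
  expect_error(calibration_rmse(rigid_transform(diag(3), c(0, 0, 0)),
                                point_pairs(matrix(1, 1, 3), matrix(1, 1, 3))[0, ]),
               "no point pairs")

  set.seed(9)
  cp <- generate_calibration_pairs(phantom_spec(seed = 9), n_configs = 3,
                                   noise_sd = 0.2)
  est <- estimate_transform(cp$pairs)
  r0 <- calibration_rmse(est, cp$pairs)
  for (i in 1:100) {
    dR <- ppmap:::axisangle_to_rot(rnorm(3, sd = 0.003))
    tp <- rigid_transform(dR %*% est$R, est$T + rnorm(3, sd = 0.05))
    expect_gte(calibration_rmse(tp, cp$pairs), r0)
  }
})

test_that("equivariance: pre-rotating camera points rotates the estimate", {
  set.seed(4)
  cp <- generate_calibration_pairs(phantom_spec(seed = 4), n_configs = 2)
  est <- estimate_transform(cp$pairs)
  Qr <- random_rotation()
  cam2 <- as.matrix(cp$pairs[, 1:3]) %*% t(Qr)
  est2 <- estimate_transform(point_pairs(cam2, as.matrix(cp$pairs[, 4:6])))
  expect_lt(max(abs(est2$R - est$R %*% t(Qr))), 1e-8)
})

test_that("fitted RMSE grows monotonically with noise", {
  rmses <- vapply(c(0.01, 0.1, 1), function(s) {
    cp <- generate_calibration_pairs(phantom_spec(seed = 8), n_configs = 5,
                                     noise_sd = s)
    calibration_rmse(estimate_transform(cp$pairs), cp$pairs)
  }, numeric(1))
  expect_true(all(diff(rmses) > 0))
})
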