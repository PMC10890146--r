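plane_frame <- function(a, b, c, H = 40, W = 50, noise_sd = 0) {
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), times = W), H, W)
  z <- -(a * x + b * y + c)
  if (noise_sd > 0) z <- z + matrix(rnorm(H * W, sd = noise_sd), H, W)
  depth_frame(z)
}

test_that("average_depth_frames: identity, arithmetic mean, noise reduction", {
  f <- plane_frame(0.1, 0.2, -3)
  expect_equal(average_depth_frames(list(f))$values, f$values)

  f4 <- depth_frame(matrix(4, 5, 6)); f6 <- depth_frame(matrix(6, 5, 6))
  expect_equal(average_depth_frames(list(f4, f6))$values, matrix(5, 5, 6))

  set.seed(11)
  truth <- plane_frame(0.05, -0.03, -500, H = 30, W = 30)$values
  stack <- lapply(1:50, function(i)
    depth_frame(truth + matrix(rnorm(900, sd = 1), 30, 30)))
  avg <- average_depth_frames(stack)
  dev <- avg$values - truth
  # per-pixel SD of a 50-frame mean of sigma = 1 noise is 1/sqrt(50)
  expect_equal(sd(dev), 1 / sqrt(50), tolerance = 0.15)

  expect_error(average_depth_frames(list()), "at least one")
  expect_error(average_depth_frames(list(f4, depth_frame(matrix(1, 2, 2)))),
               "mismatched")
})

test_that("averaging masks: a pixel invalid anywhere is invalid in the mean", {
  v1 <- matrix(1, 3, 3); m1 <- matrix(TRUE, 3, 3); m1[2, 2] <- FALSE
  avg <- average_depth_frames(list(depth_frame(v1, m1), depth_frame(v1)))
  expect_false(avg$valid_mask[2, 2])
  expect_equal(sum(avg$valid_mask), 8L)
})

test_that("fit_base_plane recovers exact planes and matches the closed-form oracle", {
  # flat frame z = 5 -> (0, 0, -5)
  flat <- fit_base_plane(depth_frame(matrix(5, 20, 20)), n_samples = 1e6)
  expect_equal(c(flat$a, flat$b, flat$c), c(0, 0, -5), tolerance = 1e-12)

  f <- plane_frame(0.1, 0.2, -3, H = 100, W = 100)
  p <- fit_base_plane(f, n_samples = 1e6)
  expect_lt(max(abs(c(p$a - 0.1, p$b - 0.2, p$c + 3))), 1e-9)

  # agreement with the hand-summed normal-equations oracle on noisy data
  set.seed(7)
  fn <- plane_frame(0.1, 0.2, -3, H = 60, W = 60, noise_sd = 0.5)
  pf <- fit_base_plane(fn, n_samples = 1e6)
  idx <- which(fn$valid_mask)
  o <- oracle_plane_fit((idx - 1) %/% 60, (idx - 1) %% 60, fn$values[idx])
  expect_lt(max(abs(c(pf$a - o$a, pf$b - o$b, pf$c - o$c))), 1e-8)
})

test_that("fit_base_plane: noisy recovery stays within 3 normal-equation SEs", {
  set.seed(21)
  cover <- replicate(20, {
    f <- plane_frame(0.1, 0.2, -3, H = 100, W = 100, noise_sd = 0.5)
    p <- fit_base_plane(f, n_samples = 10000L)
    idx <- which(f$valid_mask)
    se <- oracle_plane_se((idx - 1) %/% 100, (idx - 1) %% 100, 0.5)
    all(abs(c(p$a - 0.1, p$b - 0.2, p$c + 3)) < 3 * se)
  })
  expect_gte(mean(cover), 0.95)
})

test_that("fit_base_plane rejects degenerate geometry", {
  v <- matrix(NA_real_, 10, 10)
  v[3, ] <- 5                       # one row: collinear points
  expect_error(fit_base_plane(depth_frame(v)), "collinear|degenerate")
  v2 <- matrix(NA_real_, 10, 10); v2[1, 1] <- 1; v2[2, 2] <- 2
  expect_error(fit_base_plane(depth_frame(v2)), "fewer than 3")
})

test_that("fit is optimal and order-invariant", {
  set.seed(3)
  f <- plane_frame(0.02, -0.05, -400, H = 40, W = 40, noise_sd = 0.3)
  p <- fit_base_plane(f, n_samples = 1e6)
  r0 <- plane_residual(f, p)
  for (i in 1:100) {
    q <- plane_model(p$a + rnorm(1, sd = 0.01), p$b + rnorm(1, sd = 0.01),
                     p$c + rnorm(1, sd = 0.5))
    expect_gte(plane_residual(f, q), r0)
  }
  # order invariance: same sampled set in any order gives the same solution
  idx <- which(f$valid_mask)
  x <- (idx - 1) %/% 40; y <- (idx - 1) %% 40; z <- f$values[idx]
  perm <- sample(length(idx))
  p1 <- ppmap:::fit_plane_points(x, y, z)
  p2 <- ppmap:::fit_plane_points(x[perm], y[perm], z[perm])
  expect_equal(c(p1$a, p1$b, p1$c), c(p2$a, p2$b, p2$c), tolerance = 1e-10)
})

test_that("correct_depth applies the compensation exactly", {
  f <- plane_frame(0.1, 0.2, -3, H = 50, W = 60)
  p <- fit_base_plane(f, n_samples = 1e6)
  corr <- correct_depth(f, p)
  expect_lt(max(abs(corr$values)), 1e-6)      # exact recovery invariant

  # identity plane
  id <- correct_depth(f, plane_model(0, 0, 0))
  expect_equal(id$values, f$values)

  # inclined plane with a 10 mm box: background ~0, box height ~10
  sp <- phantom_spec(seed = 5)
  sc <- generate_depth_scene(sp, n_frames = 30, with_box = TRUE)
  avg <- average_depth_frames(sc$frames)
  fit <- fit_base_plane(depth_frame(
    ifelse(sc$truth$box_mask, NA_real_, avg$values)), n_samples = 1e6)
  corr2 <- correct_depth(avg, fit)
  expect_lt(abs(mean(corr2$values[!sc$truth$box_mask])), 0.05)
  expect_equal(mean(corr2$values[sc$truth$box_mask]), 10, tolerance = 0.05)
  expect_identical(corr2$valid_mask, avg$valid_mask)
})
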