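test_that("mutual_information: exact small cases", {
  half <- gray_image(cbind(matrix(0, 8, 4), matrix(1, 8, 4)))
  expect_equal(mutual_information(half, half), 1.0, tolerance = 1e-12)
  inv <- gray_image(1 - unclass(half))
  expect_equal(mutual_information(half, inv), 1.0, tolerance = 1e-12)
  const <- gray_image(matrix(0.3, 8, 8))
  expect_equal(mutual_information(half, const), 0.0, tolerance = 1e-12)
  expect_error(mutual_information(half, gray_image(matrix(0.1, 4, 4))), "mismatch")
})

test_that("mutual_information matches the brute-force oracle; symmetry; MI(a,a) = H(a)", {
  set.seed(13)
  for (rep in 1:20) {
    a <- gray_image(matrix(runif(64), 8, 8))
    b <- gray_image(matrix(runif(64), 8, 8))
    expect_equal(mutual_information(a, b, bins = 4), oracle_mi_bits(a, b, 4),
                 tolerance = 1e-12)
    expect_equal(mutual_information(a, b, bins = 4),
                 mutual_information(b, a, bins = 4), tolerance = 1e-12)
    expect_gte(mutual_information(a, b, bins = 4), 0)
    expect_equal(mutual_information(a, a, bins = 8), image_entropy(a, bins = 8),
                 tolerance = 1e-12)
  }
})

test_that("dice_score: exact cases, symmetry, and bounds", {
  a <- matrix(FALSE, 6, 6); a[2:3, 2:3] <- TRUE
  b <- matrix(FALSE, 6, 6); b[2:3, 3:4] <- TRUE
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, !a & FALSE), 0)       # disjoint (empty b)
  expect_equal(dice_score(a, b), 0.5)              # overlap 2 of 4+4
  expect_equal(dice_score(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)

  set.seed(17)
  for (rep in 1:50) {
    x <- matrix(runif(100) > 0.5, 10, 10)
    y <- matrix(runif(100) > 0.5, 10, 10)
    d <- dice_score(x, y)
    expect_equal(d, oracle_dice(x, y), tolerance = 1e-12)
    expect_equal(d, dice_score(y, x))
    lower <- max(0, (sum(x) + sum(y) - 100) * 2 / max(1, sum(x) + sum(y)))
    expect_gte(d, lower - 1e-12)
    expect_lte(d, 1)
  }
})

test_that("warp: identity, translation, approximate inverse", {
  img <- smooth_test_image(40, 50, seed = 3)
  z <- matrix(0, 40, 50)
  expect_lt(max(abs(unclass(warp(img, displacement_field(z, z))) - unclass(img))),
            1e-12)

  # pure one-pixel shift of a vertical edge
  edge <- gray_image(cbind(matrix(0, 20, 10), matrix(1, 20, 10)))
  w <- warp(edge, displacement_field(matrix(1, 20, 20), matrix(0, 20, 20)))
  expect_equal(unclass(w)[, 1:19], unclass(edge)[, 2:20], tolerance = 1e-12)

  # phi then -phi reconstructs a smooth image to < 2% RMS for |phi| <= 3 px
  big <- smooth_test_image(96, 128, seed = 4, sigma = 8)
  f <- generate_smooth_deformation(phantom_spec(seed = 5), shape = c(96, 128),
                                   amplitude = 3, scale = 24)
  back <- displacement_field(-f$u, -f$v)
  rec <- warp(warp(big, f), back)
  rms <- sqrt(mean((unclass(rec) - unclass(big))^2))
  expect_lt(rms, 0.02)
  expect_error(warp(big, displacement_field(matrix(0, 2, 2), matrix(0, 2, 2))),
               "dimensions")
})

test_that("estimate_ddf: aligned inputs stay put", {
  # fixed = moving: MI(F, warp(F, 0)) = H(F) is the global optimum, so the
  # zero field must survive optimization
  ph <- generate_specimen_pair(phantom_spec(seed = 31, deform_amplitude = 0))
  mv <- to_saturation_gray(ph$s_o)
  res <- suppressWarnings(estimate_ddf(mv, mv))
  expect_lt(mean(sqrt(res$field$u^2 + res$field$v^2)), 0.5)
  expect_gte(res$mi_after, res$mi_before)

  # cross-modality but geometrically aligned pair: alignment must be
  # preserved at the mask level (MI alone does not pin interior pixels)
  res2 <- suppressWarnings(estimate_ddf(ph$h_o, mv))
  expect_gte(res2$mi_after, res2$mi_before)
  expect_gte(res2$dice_after, 0.97)
  expect_error(estimate_ddf(smooth_test_image(10, 10), smooth_test_image(10, 10)),
               "256 x 192")
})

test_that("estimate_ddf recovers a pure 4 px translation within 1 px", {
  fx <- unclass(smooth_test_image(192, 256, seed = 7, sigma = 10))
  # make a clear foreground blob so masks are meaningful
  xs <- matrix(rep(0:255, each = 192), 192, 256)
  ys <- matrix(rep(0:191, times = 256), 192, 256)
  blob <- ((xs - 128) / 90)^2 + ((ys - 96) / 70)^2 <= 1
  fx[!blob] <- fx[!blob] * 0.05
  mv <- ppmap:::cpp_warp_bilinear(fx, matrix(4, 192, 256), matrix(0, 192, 256))
  res <- suppressWarnings(estimate_ddf(gray_image(fx), gray_image(mv)))
  fg <- foreground_mask(gray_image(fx))
  expect_lt(abs(mean(res$field$u[fg]) - (-4)), 1)
  expect_lt(abs(mean(res$field$v[fg])), 1)
})

test_that("estimate_ddf improves Dice and MI on a deformed phantom", {
  ph <- generate_specimen_pair(phantom_spec(seed = 32))
  res <- suppressWarnings(estimate_ddf(ph$h_o, to_saturation_gray(ph$s_o)))
  expect_gt(res$dice_after, res$dice_before)
  expect_gt(res$mi_after, res$mi_before)
  # determinism: identical inputs give identical results
  res2 <- suppressWarnings(estimate_ddf(ph$h_o, to_saturation_gray(ph$s_o)))
  expect_identical(res$field$u, res2$field$u)
  expect_identical(res$mi_after, res2$mi_after)
})

test_that("incremental level optimizer agrees with the from-scratch objective", {
  ph <- generate_specimen_pair(phantom_spec(seed = 33))
  Fm <- ppmap:::cpp_resize_area(unclass(ph$h_o), 48, 64)
  Mm <- ppmap:::cpp_resize_area(unclass(to_saturation_gray(ph$s_o)), 48, 64)
  g0 <- matrix(0, 4, 5)
  out <- ppmap:::cpp_optimize_level(Fm, Mm, g0, matrix(0, 4, 5), 32L, 0.05,
                                    c(2, 1), 6L)
  direct <- ppmap:::cpp_ddf_objective(Fm, Mm, out$gu, out$gv, 32L, 0.05)
  expect_equal(out$objective, direct, tolerance = 1e-9)
  expect_true(all(diff(out$trace) > -1e-9))
})
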