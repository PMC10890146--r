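test_that("poi_set validates its invariants", {
  expect_error(poi_set(matrix(numeric(0), 0, 2), 3), "non-empty")
  expect_error(poi_set(rbind(c(5, 5)), 0), "radius")
  expect_error(poi_set(rbind(c(5, 5), c(5, 5)), 2), "duplicate")
  expect_error(poi_set(rbind(c(500, 5)), 2, shape = c(100, 100)), "bounds")
})

test_that("detect_pois finds phantom dots within 1 px and errors on none", {
  ph <- generate_specimen_pair(phantom_spec(seed = 41))
  pois <- detect_pois(ph$s_poi, ph$s_o)
  truth <- ph$truth$centers
  expect_equal(nrow(pois$centers), nrow(truth))
  # match each detection to the nearest true center
  for (k in seq_len(nrow(truth))) {
    d <- sqrt(rowSums(sweep(pois$centers, 2, truth[k, ])^2))
    expect_lt(min(d), 1)
  }
  expect_error(detect_pois(ph$s_o, ph$s_o), "no POI dots")
})

test_that("detect_pois min_area filters small dots (diameter ~3 px)", {
  sp <- phantom_spec(seed = 42, dot_radius = 1.5)
  ph <- generate_specimen_pair(sp)
  # 1.5 px radius -> 9-pixel rasterized dots: removed at min_area = 20
  expect_error(suppressWarnings(detect_pois(ph$s_poi, ph$s_o, min_area = 20)),
               "no components")
  pois <- detect_pois(ph$s_poi, ph$s_o, min_area = 5)
  expect_equal(nrow(pois$centers), nrow(ph$truth$centers))
})

test_that("rasterize_poi_areas uses the pixel-center rule and rejects overlap", {
  p <- poi_set(rbind(c(50, 50)), radius = 1.5)
  r <- rasterize_poi_areas(p, c(100, 100))
  expect_equal(sum(r == 1L), 9L)                  # 3x3 block for r = 1.5
  expect_equal(sort(unique(as.vector(r))), c(0L, 1L))

  p2 <- poi_set(rbind(c(30, 30), c(33, 30)), radius = 4)
  expect_error(rasterize_poi_areas(p2, c(100, 100)), "overlap")
  p3 <- poi_set(rbind(c(2, 2)), radius = 5)
  expect_error(rasterize_poi_areas(p3, c(100, 100)), "bounds")
})

test_that("warp_poi_mask: identity, uniform shift, centroid tracking", {
  p <- poi_set(rbind(c(40, 30), c(70, 50)), radius = 4)
  mask <- rasterize_poi_areas(p, c(80, 100))
  z <- matrix(0, 80, 100)
  expect_identical(warp_poi_mask(mask, displacement_field(z, z)), mask)

  sh <- warp_poi_mask(mask, displacement_field(matrix(1, 80, 100), z))
  # backward shift by u = 1: content moves one pixel left
  expect_identical(sh[, 1:99], mask[, 2:100])

  # smooth deformation: warped centroid near the analytically mapped center
  ph <- generate_specimen_pair(phantom_spec(seed = 43))
  pois <- poi_set(ph$truth$centers, radius = 5)
  m <- rasterize_poi_areas(pois, dim(ph$truth$field$u))
  wm <- warp_poi_mask(m, ph$truth$field)
  for (k in seq_len(nrow(ph$truth$centers))) {
    idx <- which(wm == k)
    expect_gt(length(idx), 0)
    cy <- mean((idx - 1) %% nrow(wm)); cx <- mean((idx - 1) %/% nrow(wm))
    expect_lt(sqrt(sum((c(cx, cy) - ph$truth$mapped_centers[k, ])^2)), 2)
  }
})

test_that("extract_labels: pure regions, half-plane boundary, pie slices", {
  legend <- c("0" = "background", "1" = "connective", "2" = "tumor")
  H <- 80; W <- 100

  # disk fully inside one class
  ann1 <- annotation_map(matrix(1L, H, W), legend)
  mask <- rasterize_poi_areas(poi_set(rbind(c(50, 40)), radius = 6), c(H, W))
  rep1 <- extract_labels(mask, ann1)
  expect_equal(rep1$percent[rep1$class == "connective"], 100)
  expect_equal(rep1$percent[rep1$class == "tumor"], 0)

  # half-plane boundary through the disk center -> 50/50 +- 2 points
  lab <- matrix(1L, H, W); lab[, 51:W] <- 2L   # boundary between x=49 and x=50
  ann2 <- annotation_map(lab, legend)
  mask2 <- rasterize_poi_areas(poi_set(rbind(c(49.5, 40)), radius = 10.2), c(H, W))
  rep2 <- extract_labels(mask2, ann2)
  expect_equal(rep2$percent[rep2$class == "connective"], 50, tolerance = 0.04)
  expect_equal(rep2$percent[rep2$class == "tumor"], 50, tolerance = 0.04)

  # three-class pie slices with angular fractions 50/30/20
  legend3 <- c("0" = "bg", "1" = "a", "2" = "b", "3" = "c")
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  th <- atan2(ys - 40.5, xs - 50.5) %% (2 * pi)
  lab3 <- matrix(1L, H, W)
  lab3[th >= 2 * pi * 0.5] <- 2L
  lab3[th >= 2 * pi * 0.8] <- 3L
  mask3 <- rasterize_poi_areas(poi_set(rbind(c(50.5, 40.5)), radius = 20), c(H, W))
  rep3 <- extract_labels(mask3, annotation_map(lab3, legend3))
  expect_equal(rep3$percent[rep3$class == "a"], 50, tolerance = 0.05)
  expect_equal(rep3$percent[rep3$class == "b"], 30, tolerance = 0.08)
  expect_equal(rep3$percent[rep3$class == "c"], 20, tolerance = 0.11)
})

test_that("percentages always sum to 100 and all-background disks are flagged", {
  legend <- c("0" = "background", "1" = "fat")
  lab <- matrix(0L, 60, 60); lab[40:55, 40:55] <- 1L
  ann <- annotation_map(lab, legend)
  pois <- poi_set(rbind(c(10, 10), c(45, 45)), radius = 4)
  mask <- rasterize_poi_areas(pois, c(60, 60))
  rep <- extract_labels(mask, ann)
  sums <- tapply(rep$percent, rep$poi_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(rep$percent >= 0 & rep$percent <= 100))
  fl <- attr(rep, "flags")
  expect_equal(fl$poi_id, 1L)
  expect_equal(fl$flag, "all_background")
})

test_that("label-transfer consistency: identity DDF on self-annotation gives 100%", {
  p <- poi_set(rbind(c(30, 30), c(60, 40), c(90, 55)), radius = 5)
  mask <- rasterize_poi_areas(p, c(80, 120))
  legend <- c("0" = "background", "1" = "poi1", "2" = "poi2", "3" = "poi3")
  ann <- annotation_map(mask, legend)
  z <- matrix(0, 80, 120)
  rep <- extract_labels(warp_poi_mask(mask, displacement_field(z, z)), ann)
  for (k in 1:3) {
    own <- rep$percent[rep$poi_id == k & rep$class == paste0("poi", k)]
    expect_equal(own, 100)
  }
})
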