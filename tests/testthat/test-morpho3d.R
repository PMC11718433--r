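test_that("Otsu binarisation separates two-level and bimodal images", {
  # two-level image
  v <- array(c(10, 200)[1 + (seq_len(8000) %% 3 == 0)], c(20, 20, 20))
  b <- binarize_otsu(voxel_image(v, 1))
  expect_identical(as.vector(b$voxels), as.vector(v == 200))
  # idempotence on an already-binary image
  bb <- binarize_otsu(voxel_image(array(b$voxels * 1, dim(b$voxels)), 1))
  expect_identical(which(bb$voxels), which(b$voxels))
  # constant image rejected
  expect_error(binarize_otsu(voxel_image(array(5, c(4, 4, 4)), 1)),
               "degenerate histogram")

  # bimodal Gaussian mixture: threshold agrees with a brute-force search
  # over all 256 bins and with the independent EBImage implementation
  set.seed(7)
  v <- c(rnorm(6000, 80, 10), rnorm(4000, 180, 12))
  v <- pmin(pmax(round(v), 0), 255)
  img <- voxel_image(array(v[1:8000], c(20, 20, 20)), 1)
  thr <- attr(binarize_otsu(img), "threshold")
  vals <- as.numeric(img$voxels)
  brute <- sapply(1:254, function(t) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (length(lo) == 0 || length(hi) == 0) return(-Inf)
    length(lo) * length(hi) / length(vals)^2 * (mean(lo) - mean(hi))^2
  })
  bin_width <- diff(range(vals)) / 256
  expect_lt(abs(thr - which.max(brute)), 5 * bin_width + 5)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    eb <- EBImage::otsu(EBImage::Image(matrix(vals / 255, 100, 80)),
                        range = c(0, 1), levels = 256) * 255
    expect_lt(abs(thr - eb), 10)   # binning conventions differ by a few levels
  }
})

test_that("shell fractions recover solid, empty and random-fill balls", {
  img <- make_ball_image(150, voxel_size = 2)
  sh <- shell_hyphal_fraction(img)
  interior <- sh$shell_outer_radii <= 140
  expect_true(all(sh$fractions[interior] >= 0.99))
  # shells beyond the ball are empty
  expect_true(all(sh$fractions[sh$shell_outer_radii > 160] == 0))
  expect_error(shell_hyphal_fraction(
    voxel_image(array(FALSE, c(5, 5, 5)), 1)), "no foreground")

  img2 <- make_ball_image(150, voxel_size = 2, fill = 0.5, seed = 11)
  sh2 <- shell_hyphal_fraction(img2)
  vols <- (4 / 3) * pi * diff(c(0, sh2$shell_outer_radii^3))
  n_vox <- vols / img2$voxel_size^3
  interior <- sh2$shell_outer_radii <= 140
  sd_bin <- sqrt(0.5 * 0.5 / n_vox[interior])
  expect_true(all(abs(sh2$fractions[interior] - 0.5) < 3 * sd_bin + 1e-3))
})

test_that("fraction border interpolates to the cutoff crossing", {
  sh <- shell_profile(c(0.2, 0.2, 0.004))
  b <- border_from_fraction(sh)
  expect_equal(b, 65 + 15 * (0.2 - 0.005) / (0.2 - 0.004), tolerance = 1e-12)
  expect_gt(b, 65); expect_lt(b, 80)            # inside the third bin
  sh2 <- shell_profile(rep(0.2, 31))            # outermost radius 500
  expect_identical(border_from_fraction(sh2), 500)
  expect_error(border_from_fraction(sh, cutoff = 0.5), "no border")
})

test_that("total hyphal volume is the exact shell-volume sum", {
  sh1 <- shell_profile(rep(1, 31))              # solid sphere to 500 um
  expect_equal(total_hyphal_volume(sh1), 4 / 3 * pi * 500^3, tolerance = 1e-12)
  expect_identical(total_hyphal_volume(shell_profile(rep(0, 10))), 0)
  sh05 <- shell_profile(rep(0.5, 31))
  expect_equal(total_hyphal_volume(sh05), total_hyphal_volume(sh1) / 2,
               tolerance = 1e-12)
})

test_that("3D shape metrics classify balls and ellipsoids", {
  ball <- make_ball_image(120, voxel_size = 2)
  m <- shape_metrics_3d(ball)
  expect_gt(m$sphericity, 0.95)
  expect_gt(m$axis_ratio, 0.95)
  expect_true(m$is_spherical)

  ell <- make_ellipsoid_image(c(150, 150, 75), voxel_size = 2)
  me <- shape_metrics_3d(ell)
  expect_equal(me$axis_ratio, 0.5, tolerance = 0.05)
  expect_false(me$is_spherical)
  # both thresholds must hold simultaneously
  expect_false(pelletox:::classify_spherical(0.71, 0.94))
  expect_false(pelletox:::classify_spherical(0.69, 0.96))
  expect_true(pelletox:::classify_spherical(0.7, 0.95))
})

test_that("sphericity is scale invariant", {
  m1 <- shape_metrics_3d(make_ball_image(80, voxel_size = 2))
  m2 <- shape_metrics_3d(make_ball_image(160, voxel_size = 2))
  expect_lt(abs(m1$sphericity - m2$sphericity), 0.02)
})

test_that("convex hull reproduces closed-form areas and rejects degenerate input", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 3
  h <- convex_hull_3d(cube)
  expect_equal(h$area, 54, tolerance = 1e-9)
  expect_equal(h$volume, 27, tolerance = 1e-9)
  set.seed(5)
  u <- matrix(rnorm(3 * 800), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 10
  h2 <- convex_hull_3d(u)
  expect_equal(h2$area, 4 * pi * 100, tolerance = 0.02)
  coplanar <- cbind(matrix(runif(20), ncol = 2), 0)
  expect_error(convex_hull_3d(coplanar), "non-coplanar")
})

test_that("2D descriptors match closed forms on circle and ellipse", {
  circ <- gen_2d_mask("circle", diameter = 500)
  d <- descriptors_2d(circ)
  expect_equal(d$aesd, 500, tolerance = 0.01)
  expect_equal(d$area, pi * 250^2, tolerance = 0.01)
  expect_gt(d$solidity, 0.99)
  expect_equal(d$aspect_ratio, 1, tolerance = 0.01)
  expect_equal(d$feret_diameter, 500, tolerance = 0.01)

  ell <- gen_2d_mask("ellipse", axes = c(200, 100))
  de <- descriptors_2d(ell)
  expect_equal(de$aspect_ratio, 2, tolerance = 0.05)
  expect_equal(de$feret_diameter, 400, tolerance = 0.02)

  # degenerate single pixel
  single <- mask2d(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), 1)
  ds <- descriptors_2d(single)
  expect_identical(ds$area, 1)
  expect_equal(ds$solidity, 1, tolerance = 1e-9)
  expect_error(descriptors_2d(mask2d(matrix(FALSE, 3, 3), 1)), "empty")
})

test_that("morphology number is 1 for circles and scales as designed", {
  circ <- descriptors_2d(gen_2d_mask("circle", diameter = 400))
  expect_equal(morphology_number(circ), 1, tolerance = 0.02)
  ell <- descriptors_2d(gen_2d_mask("ellipse", axes = c(200, 100)))
  expect_lt(morphology_number(ell), 1)
  half <- circ; half$solidity <- circ$solidity / 2
  expect_equal(morphology_number(half), morphology_number(circ) / sqrt(2),
               tolerance = 1e-9)
  # scale invariance
  big <- descriptors_2d(gen_2d_mask("circle", diameter = 800))
  expect_lt(abs(morphology_number(big) - morphology_number(circ)), 0.02)
})
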