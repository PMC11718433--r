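test_that("replicate averaging is pointwise and validated", {
  p <- oxygen_profile(seq(0, 30, 10), cbind(c(0, 1, 2, 3), c(0, 1, 2, 3)))
  m <- mean_replicate_profile(p)
  expect_equal(as.vector(m$concentrations), c(0, 1, 2, 3))
  p2 <- oxygen_profile(c(0, 10), cbind(c(0, 2), c(0, 4)))
  expect_equal(as.vector(mean_replicate_profile(p2)$concentrations), c(0, 3))
  expect_error(oxygen_profile(c(0, 10, 15), matrix(0, 3, 1)), "uniform")
  expect_error(oxygen_profile(c(0, 10), matrix(-1, 2, 1)), "nonnegative")

  # mean of k noisy replicates has sd ~ sigma/sqrt(k)
  set.seed(21)
  devs <- replicate(400, {
    m3 <- rowMeans(matrix(5 + rnorm(30, sd = 0.3), 10, 3))
    m3[1] - 5
  })
  expect_equal(sd(devs), 0.3 / sqrt(3), tolerance = 0.15)
})

test_that("oxygen border interpolates the 95% crossing from the deep end", {
  # plateau at 6.7 declining inward: crossing of 0.95 * 6.7 = 6.365
  d <- seq(0, 60, 10)
  v <- c(6.7, 6.7, 6.7, 6.5, 5.0, 3.0, 1.0)     # decline starts at 30 um
  b <- oxygen_border(oxygen_profile(d, v))
  # threshold 6.365 lies between the samples 6.5 (30 um) and 5.0 (40 um):
  # crossing at 30 + 10*(6.5-6.365)/(6.5-5.0)
  expect_equal(b$depth, 30 + 10 * (6.5 - 6.365) / (6.5 - 5.0), tolerance = 1e-9)
  expect_identical(b$c_max, 6.7)

  # constant profile: border at the outermost sample, with warning
  expect_warning(bc <- oxygen_border(oxygen_profile(d, rep(5, 7))), "outermost")
  expect_identical(bc$depth, 0)

  # frac = 1 puts the border at the argmax
  vm <- c(6.7, 6.6, 6.4, 6.0, 5.0, 3.0, 1.0)
  b1 <- oxygen_border(oxygen_profile(d, vm), frac = 1)
  expect_identical(b1$depth, 0)
})

test_that("alignment maps depths to radii through the shared border", {
  sh <- shell_profile(c(rep(0.2, 29), 0.004))   # fraction border near 480
  fb <- border_from_fraction(sh)
  d <- seq(0, 400, 10)
  v <- pmax(6.7 - 0.03 * pmax(d - 30, 0), 0)
  a <- align_profiles(oxygen_profile(d, v), sh, border_depth = 30)
  expect_equal(a$radii, sort(fb - (d - 30)), tolerance = 1e-9)
  # depth 130 maps to radius fb - 100; depth == border depth maps to fb
  expect_true(any(abs(a$radii - (fb - 100)) < 1e-9))
  expect_true(any(abs(a$radii - fb) < 1e-9))
})

test_that("alignment round-trips synthetic pellets", {
  pr <- synth_preset("hyperbranching", seed = 8, noise_sd = 0)
  sh <- gen_radial_hyphal_fraction(pr$spec)
  o2 <- gen_oxygen_profile(sh, pr$params, pr$spec)
  truth <- attr(o2, "truth")
  a <- align_profiles(o2, sh, border_depth = truth$border_depth)
  expect_equal(a$border_radius, truth$border_radius, tolerance = 1e-9)
  # aligned concentrations equal the forward model at the aligned radii
  sim <- truth$sim
  inp <- a$in_pellet & a$radii < a$border_radius
  y_sim <- stats::approx(sim$radii * 1e6, sim$c_o2 * 1e3,
                         xout = a$radii[inp])$y
  expect_lt(max(abs(a$c_o2[inp] - y_sim)), 1e-9)
  # detected border (95% rule) lies close to the true border
  det <- oxygen_border(mean_replicate_profile(o2))
  expect_lt(abs(det$depth - truth$border_depth), 25)
})

test_that("central-difference gradients are exact for polynomials", {
  x <- 0:10
  expect_equal(max_central_gradient(3 * x + 1, 1), 3, tolerance = 1e-12)
  expect_equal(max_central_gradient(c(0, 1, 4, 9), 1), 4, tolerance = 1e-12)
  q <- (0:10)^2
  expect_equal(max_central_gradient(q, 1), 18, tolerance = 1e-12)  # 2x at x=9
  expect_error(max_central_gradient(c(1, 2), 1), "at least 3")
  expect_error(max_central_gradient(q, 1, coords = x, window = c(100, 101)),
               "window")
})

test_that("penetration depth follows the threshold-crossing geometry", {
  sh <- shell_profile(c(rep(0.2, 30), 0.004))
  fb <- border_from_fraction(sh)
  mk <- function(conc, radii) {
    structure(list(radii = radii, ch = rep(0.2, length(radii)), c_o2 = conc,
                   in_pellet = rep(TRUE, length(radii)), c_max = max(conc),
                   border_radius = fb, shells = sh), class = "aligned_pellet")
  }
  r <- seq(0, fb, 10)
  # zero below r = 300: depth = border - 300
  v <- ifelse(r <= 300, 0, (r - 300) * 0.05)
  a <- mk(v, r)
  expect_equal(penetration_depth(a, 0), fb - 300, tolerance = 10)
  # fully oxygenated: depth = border radius
  expect_identical(penetration_depth(mk(rep(5, length(r)), r)), fb)
  # fully anoxic: zero depth with warning
  expect_warning(d0 <- penetration_depth(mk(rep(0, length(r)), r)), "no oxygen")
  expect_identical(d0, 0)
  # monotone non-increasing in the threshold
  v2 <- pmax((r - 200) * 0.03, 0)
  d_thr <- sapply(c(0.01, 0.05, 0.2, 1), function(t) penetration_depth(mk(v2, r), t))
  expect_true(all(diff(d_thr) <= 1e-9))
})

test_that("APP matches the closed-form sphere-shell geometry", {
  sh <- shell_profile(rep(0.2, 31))             # uniform ch to 500 um
  r <- seq(0, 500, 10)
  a <- structure(list(radii = r, ch = rep(0.2, length(r)),
                      c_o2 = rep(1, length(r)), in_pellet = rep(TRUE, length(r)),
                      c_max = 6.7, border_radius = 500, shells = sh),
                 class = "aligned_pellet")
  expect_equal(active_part_percentage(a, depth = 500), 100, tolerance = 1e-9)
  expect_equal(active_part_percentage(a, depth = 0), 0, tolerance = 1e-9)
  expect_equal(active_part_percentage(a, depth = 200),
               100 * (1 - (300 / 500)^3), tolerance = 0.01)
  # monotone in depth
  apps <- sapply(seq(0, 500, 50), function(d) active_part_percentage(a, depth = d))
  expect_true(all(diff(apps) >= 0))
  expect_error(active_part_percentage(a, depth = 600), "border_radius")
})

test_that("strain-typical presets give penetration depths in the measured range", {
  # measured supplied layers are 90-290 um deep, strain-specific; the
  # synthetic presets emulate that regime
  for (ps in c("regular", "hyperbranching")) {
    pr <- synth_preset(ps, seed = 2)
    sh <- gen_radial_hyphal_fraction(pr$spec)
    o2 <- gen_oxygen_profile(sh, pr$params, pr$spec)
    a <- align_profiles(o2, sh, border_depth = attr(o2, "truth")$border_depth)
    d <- penetration_depth(a)
    expect_gt(d, 90); expect_lt(d, 290)
  }
})

test_that("profile CSV round-trips", {
  p <- oxygen_profile(seq(0, 50, 10), matrix(runif(18, 0, 6.7), 6, 3))
  f <- tempfile(fileext = ".csv")
  write_profile_csv(p, f)
  p2 <- read_profile_csv(f)
  expect_equal(p2$depths, p$depths)
  expect_equal(unname(p2$concentrations), unname(p$concentrations),
               tolerance = 1e-9)
  unlink(f)
})
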