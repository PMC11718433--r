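test_that("effective diffusivity follows the hindrance power law", {
  p <- kinetic_params()
  expect_identical(effective_diffusion(0, p), p$d_bulk)
  expect_equal(effective_diffusion(0.2, p), 8.7e-6 * 0.8^1.76, tolerance = 1e-12)
  ch <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(effective_diffusion(ch, p)) < 0))
  expect_lt(effective_diffusion(0.999, p) / p$d_bulk, 1e-5)
  expect_error(effective_diffusion(1, p), "diffusivity")
})

test_that("consumption kinetics match hand-computed limits", {
  p <- kinetic_params()
  expect_identical(q_growth(0, 0.1, p), 0)
  expect_identical(q_growth(1, 0, p), 0)
  # saturation: c >> k_xo
  expect_equal(q_growth(1, 0.1, p), 150 / 2.77 * 0.16 * 0.1 * (1 / (1 + 2.5e-5)),
               tolerance = 1e-6)
  expect_equal(q_growth(1e3, 0.1, p), 0.8664, tolerance = 1e-3)
  pm <- kinetic_params(variant = "growth_plus_maintenance")
  expect_identical(q_maintenance_variant(0, 0.1, pm), 0)
  # below c_crit the growth term is floored at zero but maintenance remains
  q_low <- q_maintenance_variant(pm$c_crit / 2, 0.1, pm)
  expect_gt(q_low, 0)
  expect_equal(q_low, pm$m_o2_max * pm$rho_h * 0.1 *
                 (pm$c_crit / 2) / (pm$k_mo + pm$c_crit / 2), tolerance = 1e-12)
  expect_equal(q_maintenance_variant(1e3, 0.1, pm),
               150 * 0.1 * (0.16 / 2.77 + 7.2e-3), tolerance = 1e-3)
})

test_that("shell profiles interpolate onto the simulation grid as specified", {
  sh <- shell_profile(rep(0.2, 5))
  expect_equal(fraction_to_grid(sh, 50, 100), rep(0.2, 50))
  # two bins 0.1 / 0.3: value midway between the bin mid-radii is 0.2
  sh2 <- shell_profile(c(0.1, 0.3), core_radius = 50, shell_width = 15)
  g <- fraction_to_grid(sh2, 231, 65)            # nodes every 65/230 um
  mid <- (25 + 57.5) / 2                          # midpoint of bin mid-radii
  expect_equal(g[which.min(abs(seq(0, 65, length.out = 231) - mid))], 0.2,
               tolerance = 1e-3)
  expect_warning(fraction_to_grid(shell_profile(c(1, 1)), 10, 60), "clamped")
  expect_error(fraction_to_grid(sh, 50, 1e4), "exceeds")
})

test_that("steady state is flat without any oxygen sink", {
  cs <- 6.7e-3
  p0 <- kinetic_params(mu_max = 0, m_o2_max = 0)
  s <- steady_state_profile(rep(0.2, 60), p0, cs, 3e-4)
  expect_equal(s$c_o2, rep(cs, 60), tolerance = 1e-9)
  s2 <- steady_state_profile(rep(0, 60), kinetic_params(), cs, 3e-4)
  expect_equal(s2$c_o2, rep(cs, 60), tolerance = 1e-9)
})

test_that("solver matches the analytic first-order sphere solution", {
  # k_xo scaled far above c so Monod kinetics are effectively first order
  cs <- 6.7e-3; R <- 250e-6; chv <- 0.3
  p <- kinetic_params(rho_h = 15000, mu_max = 8, k_xo = 6.7)
  k1 <- p$rho_h * p$mu_max * chv / (p$y_xo2 * p$k_xo)
  phi <- R * sqrt(k1 / effective_diffusion(chv, p))
  exact <- function(r) ifelse(r == 0, cs * phi / sinh(phi),
                              cs * (R / r) * sinh(phi * r / R) / sinh(phi))
  s <- steady_state_newton(rep(chv, 100), p, cs, R)
  expect_lt(max(abs(s$c_o2 - exact(s$radii)) / exact(s$radii)), 0.01)
})

test_that("transient integration and Newton solve agree", {
  p <- kinetic_params()
  cs <- 6.7e-3
  st <- steady_state_profile(rep(0.15, 80), p, cs, 4e-4, n_nodes = 80)
  sn <- steady_state_newton(rep(0.15, 80), p, cs, 4e-4, n_nodes = 80)
  expect_true(st$converged)
  expect_lt(max(abs(st$c_o2 - sn$c_o2)) / cs, 1e-4)
})

test_that("steady-state profile is monotone and bounded", {
  p <- kinetic_params()
  for (chv in c(0.1, 0.3)) {
    s <- steady_state_newton(rep(chv, 100), p, 6.7e-3, 4e-4)
    expect_true(all(diff(s$c_o2) > -1e-12))
    expect_true(all(s$c_o2 >= 0 & s$c_o2 <= 6.7e-3 + 1e-12))
    expect_equal(s$c_o2[100], 6.7e-3)
  }
})

test_that("doubling the grid changes the default scenario by < 0.5%", {
  p <- kinetic_params()
  cs <- 6.7e-3; R <- 4e-4
  sh <- gen_radial_hyphal_fraction(synth_spec(pellet_radius = 400))
  s100 <- steady_state_newton(sh, p, cs, R, n_nodes = 100)
  s200 <- steady_state_newton(sh, p, cs, R, n_nodes = 200)
  on100 <- stats::approx(s200$radii, s200$c_o2, xout = s100$radii, rule = 2)$y
  expect_lt(max(abs(s100$c_o2 - on100)) / cs, 0.005)
})

test_that("a dense pellet develops an anoxic core that grows with radius", {
  p <- kinetic_params()
  cs <- 6.7e-3
  core_radius <- function(R) {
    s <- steady_state_newton(rep(0.35, 100), p, cs, R)
    idx <- which(s$c_o2 < 1e-3 * cs)
    if (length(idx) == 0) 0 else max(s$radii[idx])
  }
  a1 <- core_radius(400e-6); a2 <- core_radius(550e-6)
  expect_gt(a1, 0)
  expect_gt(a2, a1)
})

test_that("boundary flux balances volume-integrated consumption", {
  p <- kinetic_params()
  cs <- 6.7e-3; R <- 4e-4; n <- 100
  s <- steady_state_newton(rep(0.2, n), p, cs, R, n_nodes = n)
  r <- s$radii; dr <- r[2] - r[1]
  dcdr <- (3 * s$c_o2[n] - 4 * s$c_o2[n - 1] + s$c_o2[n - 2]) / (2 * dr)
  flux <- 4 * pi * R^2 * effective_diffusion(0.2, p) * dcdr
  q <- q_oxygen(s$c_o2, s$ch, p)
  cons <- 4 * pi * sum((q[-1] * r[-1]^2 + q[-n] * r[-n]^2) / 2) * dr
  expect_lt(abs(flux - cons) / cons, 0.01)
})

test_that("characteristic times reproduce the expected scales", {
  p <- kinetic_params()
  ct <- characteristic_times(p, 200e-6, 6.7e-3, 0.1)
  expect_equal(ct$t_doubling, log(2) / 0.16, tolerance = 1e-12)
  expect_equal(ct$t_diffusion, (200e-6)^2 / effective_diffusion(0.1, p),
               tolerance = 1e-12)
  expect_equal(ct$t_diffusion, 5.6e-3, tolerance = 0.01)
  ct2 <- characteristic_times(kinetic_params(mu_max = 0.32), 200e-6, 6.7e-3, 0.1)
  expect_equal(ct2$t_doubling, ct$t_doubling / 2, tolerance = 1e-12)
  expect_identical(characteristic_times(kinetic_params(mu_max = 0),
                                        1e-4, 1e-3, 0.1)$t_doubling, Inf)
})

test_that("tridiagonal solver matches dense solve", {
  set.seed(3)
  n <- 40
  lo <- runif(n - 1); up <- runif(n - 1); dg <- runif(n) + 3
  A <- diag(dg)
  A[cbind(2:n, 1:(n - 1))] <- lo
  A[cbind(1:(n - 1), 2:n)] <- up
  b <- rnorm(n)
  expect_equal(pelletox:::solve_tridiag(lo, dg, up, b), solve(A, b),
               tolerance = 1e-10)
})

test_that("complex-step derivative matches central differences on smooth maps", {
  fs <- list(function(x) x^3 + sin(x),
             function(x) 1 / (x + 2),
             function(x) exp(-x) * sqrt(x + 3))
  for (f in fs) for (x0 in c(0.3, 1.7)) {
    cs <- complex_step_derivative(f, x0)
    h <- 1e-6
    fd <- (f(x0 + h) - f(x0 - h)) / (2 * h)
    expect_equal(cs, fd, tolerance = 1e-5)
  }
})
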