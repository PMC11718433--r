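#' Specification of a synthetic pellet
#'
#' Describes the phantom geometry and the radial hyphal-fraction profile of
#' a seeded synthetic pellet: the hyphal fraction transitions smoothly
#' (logistically) from `core_fraction` in the pellet centre to
#' `rim_fraction` in the outer region over `rim_width`, then declines
#' sharply to (almost) zero at the pellet border so that the
#' border-detection cutoff rule recovers `pellet_radius`.
#'
#' @param pellet_radius pellet border radius, um (>= 65 so at least one
#'   shell fits around the 50 um core).
#' @param core_fraction hyphal volume fraction in the centre, in \[0, 1).
#' @param rim_fraction hyphal volume fraction in the outer region, in \[0, 1).
#' @param rim_width width of the core-to-rim transition zone, um.
#' @param geometry `"sphere"` or `"ellipsoid"`.
#' @param axes semi-axes of the ellipsoid, um (length 3); ignored for
#'   spheres.
#' @param noise_sd oxygen sensor noise, mg L^-1 (Gaussian, truncated at 0).
#' @param sensor_step microelectrode depth step, um (default 10).
#' @param voxel_size phantom voxel edge, um (default 2; measured images are
#'   finer, but synthetic phantoms stay desk-scale at 2 um).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(pellet_radius = 300,
                       core_fraction = 0.2,
                       rim_fraction = 0.15,
                       rim_width = 100,
                       geometry = c("sphere", "ellipsoid"),
                       axes = NULL,
                       noise_sd = 0.03,
                       sensor_step = 10,
                       voxel_size = 2,
                       seed = 1L) {
  geometry <- match.arg(geometry)
  if (pellet_radius <= 0) stop_pellet("pellet_radius must be positive")
  for (f in c(core_fraction, rim_fraction))
    if (f < 0 || f >= 1) stop_pellet("fractions must lie in [0, 1)")
  if (noise_sd < 0) stop_pellet("noise_sd must be nonnegative")
  if (rim_width <= 0 || sensor_step <= 0 || voxel_size <= 0)
    stop_pellet("rim_width, sensor_step and voxel_size must be positive")
  if (geometry == "ellipsoid") {
    if (is.null(axes) || length(axes) != 3 || any(axes <= 0))
      stop_pellet("ellipsoid geometry requires 3 positive semi-axes")
  } else axes <- rep(pellet_radius, 3)
  structure(list(pellet_radius = pellet_radius, core_fraction = core_fraction,
                 rim_fraction = rim_fraction, rim_width = rim_width,
                 geometry = geometry, axes = axes, noise_sd = noise_sd,
                 sensor_step = sensor_step, voxel_size = voxel_size,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Strain-style presets for synthetic pellets
#'
#' Two qualitative morphotypes: `"regular"` (looser, slightly denser core,
#' larger pellet) and `"hyperbranching"` (denser outer region, smaller
#' pellet), paired with the matching growth-rate preset of
#' [strain_params()]. The presets emulate the qualitative shape of measured
#' radial hyphal-fraction profiles; they are not digitised measurements.
#'
#' @param preset `"regular"` or `"hyperbranching"`.
#' @param seed integer seed.
#' @param ... overrides passed on to [synth_spec()].
#' @return list with elements `spec` ([synth_spec()]) and `params`
#'   ([kinetic_params()]).
#' @export
synth_preset <- function(preset = c("regular", "hyperbranching"),
                         seed = 1L, ...) {
  preset <- match.arg(preset)
  defaults <- if (preset == "regular") {
    list(pellet_radius = 450, core_fraction = 0.28,
         rim_fraction = 0.25, rim_width = 120, seed = seed)
  } else {
    list(pellet_radius = 350, core_fraction = 0.15,
         rim_fraction = 0.32, rim_width = 100, seed = seed)
  }
  spec <- do.call(synth_spec, utils::modifyList(defaults, list(...)))
  params <- strain_params(if (preset == "regular") "R" else "H")
  list(spec = spec, params = params)
}

# Continuous target hyphal fraction of a synthetic pellet (before the
# terminal border decline): logistic core-to-rim transition centred one
# rim_width inside the border.
synth_ch_base <- function(spec) {
  r_mid <- spec$pellet_radius - spec$rim_width
  s <- spec$rim_width / 6
  function(r)
    spec$rim_fraction + (spec$core_fraction - spec$rim_fraction) /
      (1 + exp((r - r_mid) / s))
}

#' Generate the radial hyphal-fraction profile of a synthetic pellet
#'
#' Shell values are the logistic core-to-rim interpolant evaluated at shell
#' mid-radii; one terminal shell beyond the border carries a fraction below
#' the border-detection cutoff (0.005), so [border_from_fraction()]
#' recovers `pellet_radius` to within one shell width.
#'
#' @param spec a [synth_spec()].
#' @param core_radius,shell_width shell geometry, um.
#' @return a [shell_profile()].
#' @export
gen_radial_hyphal_fraction <- function(spec, core_radius = 50, shell_width = 15) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$pellet_radius < core_radius + shell_width)
    stop_pellet("pellet_radius %g um too small: no shell fits around the %g um core",
                spec$pellet_radius, core_radius)
  n_shell <- floor((spec$pellet_radius - core_radius) / shell_width)
  r_out <- core_radius + shell_width * (0:n_shell)
  r_in <- c(0, r_out[-length(r_out)])
  mids <- (r_in + r_out) / 2
  f <- synth_ch_base(spec)(mids)
  # terminal decline: sub-cutoff shell just beyond the border
  r_out <- c(r_out, r_out[length(r_out)] + shell_width)
  f <- c(f, 0.001)
  shell_profile(pmin(pmax(f, 0), 0.999), core_radius = core_radius,
                shell_width = shell_width, voxel_size = spec$voxel_size,
                shell_outer_radii = r_out)
}

#' Generate noisy microelectrode oxygen profiles from the forward model
#'
#' Computes the steady-state oxygen profile of the reaction-diffusion model
#' for the given shell profile and kinetics, samples it at the sensor step
#' from the pellet border inward, prepends a 100 um outside-pellet plateau
#' at the surface concentration (the approach region of a real
#' measurement), and adds Gaussian sensor noise truncated at zero. The
#' noise is signal-proportional (standard deviation `noise_sd` at the
#' surface concentration, scaling linearly with the local concentration):
#' amperometric sensor noise scales with the measured current, and the
#' zero-oxygen reading is the sensor's stable calibration point, so anoxic
#' regions read (near) zero without a truncation bias.
#'
#' @param shells a [shell_profile()] (e.g. from
#'   [gen_radial_hyphal_fraction()]).
#' @param params a [kinetic_params()] object.
#' @param spec a [synth_spec()] (noise, sensor step, seed).
#' @param c_surface surface oxygen concentration, mg L^-1 (default 6.7,
#'   air saturation at 37 degC).
#' @param n_replicates replicate profiles (default 3).
#' @param n_nodes simulation nodes.
#' @return an [oxygen_profile()]; the generating ground truth (border
#'   radius, noiseless concentrations, simulation) is attached as
#'   attribute `"truth"`.
#' @export
gen_oxygen_profile <- function(shells, params, spec, c_surface = 6.7,
                               n_replicates = 3, n_nodes = 100) {
  stopifnot(inherits(shells, "shell_profile"), inherits(params, "kinetic_params"),
            inherits(spec, "synth_spec"))
  border <- border_from_fraction(shells)
  sim <- steady_state_newton(shells, params, c_surface * MGL_TO_KGM3,
                             border * UM_TO_M, n_nodes = n_nodes)
  approach <- 100                                  # um of plateau outside
  step <- spec$sensor_step
  depths <- seq(0, approach + floor(border / step) * step, by = step)
  radii <- border - (depths - approach)
  truth <- ifelse(radii >= border, c_surface,
                  interp1(sim$radii / UM_TO_M, sim$c_o2 / MGL_TO_KGM3, radii))
  conc <- with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(length(depths) * n_replicates,
                                 sd = spec$noise_sd),
                    length(depths), n_replicates)
    pmax(truth + noise * (truth / c_surface), 0)
  })
  out <- oxygen_profile(depths, conc)
  attr(out, "truth") <- list(border_radius = border, border_depth = approach,
                             concentrations = truth, sim = sim,
                             c_surface = c_surface)
  out
}

#' Generate a 3D voxel phantom matching a target shell profile
#'
#' Every voxel whose centre lies at (scaled) radius r from the image centre
#' is set to foreground with probability equal to the target hyphal
#' fraction of the bin containing r, so shell-wise voxel counting recovers
#' the target profile up to binomial sampling error. Ellipsoid geometry
#' scales the three axes anisotropically (the largest semi-axis maps to the
#' shell radius).
#'
#' @param target a [shell_profile()] with the per-bin foreground
#'   probabilities.
#' @param spec a [synth_spec()] (geometry, voxel size, seed).
#' @param margin background margin around the pellet, um.
#' @return binary [voxel_image()].
#' @export
gen_pellet_image <- function(target, spec, margin = 10) {
  stopifnot(inherits(target, "shell_profile"), inherits(spec, "synth_spec"))
  r_shell_max <- max(target$shell_outer_radii)
  if (r_shell_max > 600)
    stop_pellet("target radius %g um too large for a phantom (max 600 um)", r_shell_max)
  vs <- spec$voxel_size
  scale <- spec$axes / max(spec$axes)
  half <- scale * (r_shell_max + margin)
  d <- pmax(2L * as.integer(ceiling(half / vs)), 3L)
  cen <- d / 2 * vs
  ax <- function(k) ((seq_len(d[k]) - 0.5) * vs - cen[k]) / scale[k]
  r_eff <- sqrt(outer(outer(ax(1)^2, ax(2)^2, "+"), ax(3)^2, "+"))
  breaks <- c(0, target$shell_outer_radii)
  bin <- findInterval(r_eff, breaks, left.open = TRUE)
  bin <- bin + (r_eff == 0)
  prob <- c(target$fractions, 0)[pmin(bin, length(target$fractions) + 1L)]
  fg <- with_seed(spec$seed,
                  array(stats::runif(length(r_eff)) < prob, d))
  voxel_image(fg, vs)
}

#' Generate a filled 2D mask (circle or ellipse)
#'
#' Fixture generator for the 2D Euclidean shape descriptors.
#'
#' @param shape `"circle"` or `"ellipse"`.
#' @param diameter circle diameter, um.
#' @param axes semi-axes (a, b) of the ellipse, um.
#' @param pixel_size pixel edge, um.
#' @param margin background margin, um.
#' @return a [mask2d()].
#' @export
gen_2d_mask <- function(shape = c("circle", "ellipse"), diameter = NULL,
                        axes = NULL, pixel_size = 1, margin = 5) {
  shape <- match.arg(shape)
  if (shape == "circle") {
    if (is.null(diameter) || diameter <= 0) stop_pellet("circle needs a positive diameter")
    axes <- rep(diameter / 2, 2)
  } else if (is.null(axes) || length(axes) != 2 || any(axes <= 0))
    stop_pellet("ellipse needs 2 positive semi-axes")
  d <- 2L * as.integer(ceiling((axes + margin) / pixel_size))
  cen <- d / 2 * pixel_size
  x <- ((seq_len(d[1]) - 0.5) * pixel_size - cen[1]) / axes[1]
  y <- ((seq_len(d[2]) - 0.5) * pixel_size - cen[2]) / axes[2]
  mask2d(outer(x^2, y^2, "+") <= 1, pixel_size)
}
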