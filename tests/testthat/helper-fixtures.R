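# Shared fixture builders: all fixtures are generated in code at test time.

# Solid (or partially filled) ball phantom: voxels within `radius_um` of the
# image centre are foreground with probability `fill`.
make_ball_image <- function(radius_um, voxel_size = 2, fill = 1, margin = 10,
                            seed = 1) {
  d <- 2L * as.integer(ceiling((radius_um + margin) / voxel_size))
  cen <- d / 2 * voxel_size
  ax <- ((seq_len(d) - 0.5) * voxel_size - cen)
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  inside <- r <= radius_um
  if (fill < 1) {
    set.seed(seed)
    inside <- inside & array(runif(length(r)) < fill, dim(r))
  }
  voxel_image(inside, voxel_size)
}

# Solid ellipsoid phantom with semi-axes (um).
make_ellipsoid_image <- function(axes, voxel_size = 2, margin = 10) {
  d <- 2L * as.integer(ceiling((axes + margin) / voxel_size))
  cen <- d / 2 * voxel_size
  ax <- function(k) (((seq_len(d[k]) - 0.5) * voxel_size) - cen[k]) / axes[k]
  rho <- sqrt(outer(outer(ax(1)^2, ax(2)^2, "+"), ax(3)^2, "+"))
  voxel_image(rho <= 1, voxel_size)
}

# Aligned pellet built directly from a forward simulation: exact geometry,
# no border detection, for estimation tests.
make_true_aligned <- function(shells, params, c_surface = 6.7, step = 10,
                              noise_sd = 0, seed = 1, n_replicates = 3) {
  spec <- synth_spec(pellet_radius = max(shells$shell_outer_radii) - 1,
                     noise_sd = noise_sd, sensor_step = step, seed = seed)
  o2 <- gen_oxygen_profile(shells, params, spec, c_surface = c_surface,
                           n_replicates = n_replicates)
  align_profiles(o2, shells, border_depth = attr(o2, "truth")$border_depth)
}

# A small family of varied synthetic shell profiles for recovery studies.
varied_shells <- function(i) {
  spec <- synth_spec(pellet_radius = 320 + 20 * (i %% 5),
                     core_fraction = 0.15 + 0.02 * (i %% 4),
                     rim_fraction = 0.22 + 0.02 * (i %% 3),
                     rim_width = 90 + 10 * (i %% 3),
                     seed = i)
  gen_radial_hyphal_fraction(spec)
}
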