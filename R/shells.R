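#' Radial hyphal-fraction profile in spherical shells
#'
#' Container for the shell-resolved hyphal volume fraction ch(r): a central
#' sphere (default radius 50 um) surrounded by concentric shells of fixed
#' width (default 15 um). The first bin is the central sphere; each entry of
#' `fractions` is the hyphal volume in the bin divided by the bin volume.
#'
#' @param fractions hyphal volume fraction per bin, each in \[0, 1\].
#' @param core_radius radius of the central sphere, um.
#' @param shell_width width of each shell, um.
#' @param voxel_size voxel edge length of the source image, um (NA when the
#'   profile was not derived from an image).
#' @param shell_outer_radii optional explicit outer radii, um, strictly
#'   increasing, first equal to `core_radius`. Derived from `core_radius`
#'   and `shell_width` when omitted.
#' @return object of class `shell_profile`.
#' @export
shell_profile <- function(fractions, core_radius = 50, shell_width = 15,
                          voxel_size = NA_real_, shell_outer_radii = NULL) {
  fractions <- as.numeric(fractions)
  if (length(fractions) < 1L) stop_pellet("at least one bin required")
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1))
    stop_pellet("shell fractions must lie in [0, 1]")
  if (core_radius <= 0 || shell_width <= 0)
    stop_pellet("core_radius and shell_width must be positive")
  if (is.null(shell_outer_radii))
    shell_outer_radii <- core_radius + shell_width * (seq_along(fractions) - 1L)
  if (length(shell_outer_radii) != length(fractions))
    stop_pellet("shell_outer_radii and fractions lengths differ")
  if (any(diff(shell_outer_radii) <= 0) || shell_outer_radii[1] != core_radius)
    stop_pellet("shell_outer_radii must be strictly increasing, starting at core_radius")
  structure(list(core_radius = core_radius, shell_width = shell_width,
                 shell_outer_radii = shell_outer_radii,
                 fractions = fractions, voxel_size = voxel_size),
            class = "shell_profile")
}

#' @export
print.shell_profile <- function(x, ...) {
  cat(sprintf("Shell profile: core %g um + %d shells of %g um (outer radius %g um)\n",
              x$core_radius, length(x$fractions) - 1L, x$shell_width,
              max(x$shell_outer_radii)))
  cat(sprintf("  hyphal fraction range %.4f - %.4f\n",
              min(x$fractions), max(x$fractions)))
  invisible(x)
}

#' @export
as.data.frame.shell_profile <- function(x, ...) {
  data.frame(shell_outer_radius_um = x$shell_outer_radii, fraction = x$fractions)
}

# Representative radius of each bin: centre of the core sphere bin is taken
# at r = 0..core; for interpolation the core is treated as constant and the
# shells are anchored at their mid-radii.
shell_mid_radii <- function(shells) {
  r_out <- shells$shell_outer_radii
  r_in <- c(0, r_out[-length(r_out)])
  (r_in + r_out) / 2
}

# Exact bin volumes, um^3.
shell_bin_volumes <- function(shells) {
  r_out <- shells$shell_outer_radii
  r_in <- c(0, r_out[-length(r_out)])
  4 / 3 * pi * (r_out^3 - r_in^3)
}

#' Continuous interpolant of a shell profile
#'
#' Piecewise-linear interpolation of ch between shell mid-radii, constant
#' below the innermost anchor (centre of the core sphere) and beyond the
#' outermost one, optionally declining linearly to zero at `border` with
#' zero beyond. Returned as a function of radius (um).
#'
#' @param shells a [shell_profile()].
#' @param border optional pellet border radius (um) at which ch reaches 0.
#' @return function mapping radius (um) to hyphal fraction, clamped to \[0, 1\].
#' @export
ch_interpolant <- function(shells, border = NULL) {
  mids <- shell_mid_radii(shells)
  f <- shells$fractions
  xs <- c(0, mids)
  ys <- c(f[1], f)
  if (!is.null(border)) {
    keep <- xs < border
    xs <- c(xs[keep], border)
    ys <- c(ys[keep], 0)
  }
  # de-duplicate knots that collide (tiny border just past a mid-radius)
  ok <- !duplicated(xs)
  xs <- xs[ok]; ys <- ys[ok]
  function(r) {
    v <- interp1(xs, ys, r)
    if (!is.null(border)) v[r >= border] <- 0
    pmin(pmax(v, 0), 1)
  }
}

#' Total hyphal volume of a pellet
#'
#' Sum over bins of fraction times exact spherical bin volume.
#'
#' @param shells a [shell_profile()].
#' @return total hyphal volume, um^3.
#' @export
total_hyphal_volume <- function(shells) {
  stopifnot(inherits(shells, "shell_profile"))
  sum(shells$fractions * shell_bin_volumes(shells))
}

#' Pellet border radius from the hyphal-fraction profile
#'
#' The pellet border is placed where the hyphal fraction falls to a small
#' cutoff (default 0.005 rather than exactly 0, so that a single protruding
#' hypha does not drag the border outwards): the outer radius of the
#' outermost bin still at or above the cutoff, linearly interpolated against
#' the next bin's fraction to the exact crossing.
#'
#' @param shells a [shell_profile()].
#' @param cutoff hyphal-fraction cutoff defining the border (default 0.005).
#' @return border radius, um.
#' @export
border_from_fraction <- function(shells, cutoff = 0.005) {
  stopifnot(inherits(shells, "shell_profile"))
  f <- shells$fractions
  r <- shells$shell_outer_radii
  idx <- which(f >= cutoff)
  if (length(idx) == 0L)
    stop_pellet("all shell fractions below cutoff %g; no border", cutoff)
  i <- max(idx)
  if (i == length(f)) return(r[i])
  # linear crossing between the outer radii of bins i and i+1
  r[i] + (r[i + 1] - r[i]) * (f[i] - cutoff) / (f[i] - f[i + 1])
}

#' Write / read a shell profile as CSV
#'
#' Columns `shell_outer_radius_um`, `fraction`.
#' @param shells a [shell_profile()]; `path` file path.
#' @param path file path.
#' @param core_radius,voxel_size metadata for [read_shells_csv()].
#' @return `read_shells_csv` returns a `shell_profile`.
#' @export
write_shells_csv <- function(shells, path) {
  utils::write.csv(as.data.frame(shells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shells_csv
#' @export
read_shells_csv <- function(path, core_radius = NULL, voxel_size = NA_real_) {
  d <- utils::read.csv(path)
  r <- d$shell_outer_radius_um
  if (is.null(core_radius)) core_radius <- r[1]
  width <- if (length(r) > 1) r[2] - r[1] else 15
  shell_profile(d$fraction, core_radius = core_radius, shell_width = width,
                voxel_size = voxel_size, shell_outer_radii = r)
}
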