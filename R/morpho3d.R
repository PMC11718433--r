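#' 3D voxel image of a pellet
#'
#' Thin container for a 3D intensity or binary grid with an isotropic
#' physical voxel size. Physical coordinates are voxel centres:
#' `(index - 0.5) * voxel_size` along each axis (1-based indices).
#'
#' @param voxels 3D array (numeric, integer or logical).
#' @param voxel_size voxel edge length, um.
#' @return object of class `voxel_image`.
#' @export
voxel_image <- function(voxels, voxel_size) {
  if (length(dim(voxels)) != 3) stop_pellet("voxels must be a 3D array")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop_pellet("voxel_size must be positive")
  structure(list(voxels = voxels, voxel_size = voxel_size),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Voxel image %d x %d x %d, voxel size %g um (%s)\n",
              d[1], d[2], d[3], x$voxel_size,
              if (is_binary_image(x)) "binary" else "grayscale"))
  invisible(x)
}

is_binary_image <- function(img) {
  is.logical(img$voxels) || all(img$voxels %in% c(0, 1))
}

#' Binarize a grayscale voxel image with Otsu's threshold
#'
#' Separates hyphal material from background by the threshold that
#' maximises the between-class variance of a 256-bin intensity histogram.
#' Already-binary images pass through with their foreground set unchanged.
#'
#' @param img a [voxel_image()] with at least two distinct intensities.
#' @return binary `voxel_image` (logical voxels) with the chosen threshold
#'   attached as attribute `"threshold"`.
#' @export
binarize_otsu <- function(img) {
  stopifnot(inherits(img, "voxel_image"))
  v <- as.numeric(img$voxels)
  rng <- range(v)
  if (rng[1] == rng[2]) stop_pellet("degenerate histogram: constant image")
  thr <- otsu_threshold(v, rng)
  out <- voxel_image(array(img$voxels > thr, dim(img$voxels)), img$voxel_size)
  attr(out, "threshold") <- thr
  out
}

# Exhaustive search over 256-bin splits for the maximal between-class
# variance; returns the threshold value (upper edge of the background class).
otsu_threshold <- function(v, rng, n_bins = 256L) {
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- findInterval(v, breaks, all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w0 <- w[-n_bins] / n
  mu0 <- m[-n_bins] / pmax(w[-n_bins], 1)
  mu1 <- (mt - m[-n_bins]) / pmax(n - w[-n_bins], 1)
  sb <- w0 * (1 - w0) * (mu0 - mu1)^2
  sb[w[-n_bins] == 0 | w[-n_bins] == n] <- -Inf
  breaks[which.max(sb) + 1L]
}

#' Shell-resolved hyphal volume fraction of a binary pellet image
#'
#' Assigns every voxel (by its centre position) to the central sphere
#' around the foreground mass centre or to one of the concentric shells,
#' and reports the foreground fraction per bin. Bins extend to the edge of
#' the image; bins truncated by the image boundary are normalised by their
#' in-image voxel count.
#'
#' @param img binary [voxel_image()].
#' @param core_radius radius of the central sphere, um (default 50).
#' @param shell_width shell width, um (default 15).
#' @return a [shell_profile()].
#' @export
shell_hyphal_fraction <- function(img, core_radius = 50, shell_width = 15) {
  stopifnot(inherits(img, "voxel_image"))
  if (!is_binary_image(img)) stop_pellet("image must be binary; run binarize_otsu()")
  fg <- img$voxels > 0
  if (!any(fg)) stop_pellet("no foreground voxels")
  vs <- img$voxel_size
  d <- dim(fg)
  cen <- foreground_centroid(fg, vs)
  dx2 <- (((seq_len(d[1]) - 0.5) * vs) - cen[1])^2
  dy2 <- (((seq_len(d[2]) - 0.5) * vs) - cen[2])^2
  dz2 <- (((seq_len(d[3]) - 0.5) * vs) - cen[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  breaks <- c(0, seq(core_radius, max(r) + shell_width, by = shell_width))
  bin <- findInterval(r, breaks, rightmost.closed = FALSE, left.open = TRUE)
  bin <- bin + (r == 0)                      # centre voxel into bin 1
  nb <- length(breaks) - 1L
  tot <- tabulate(bin, nb)
  hyp <- tabulate(bin[fg], nb)
  keep <- which(tot > 0)
  shell_profile(hyp[keep] / tot[keep],
                core_radius = core_radius, shell_width = shell_width,
                voxel_size = vs, shell_outer_radii = breaks[-1][keep])
}

foreground_centroid <- function(fg, vs) {
  d <- dim(fg)
  n <- sum(fg)
  cx <- sum(rowSums(fg, dims = 1) * (seq_len(d[1]) - 0.5)) / n * vs
  m23 <- colSums(fg, dims = 1)               # d2 x d3
  cy <- sum(rowSums(m23) * (seq_len(d[2]) - 0.5)) / n * vs
  cz <- sum(colSums(m23) * (seq_len(d[3]) - 0.5)) / n * vs
  c(cx, cy, cz)
}

# Foreground voxels with at least one 6-neighbour outside the foreground
# (or on the image boundary); these carry all convex-hull information.
surface_voxel_centers <- function(fg, vs) {
  d <- dim(fg)
  interior <- array(TRUE, d)
  shift_and <- function(arr, axis, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1) { idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1) }
    else { idx_dst[[axis]] <- 1:(d[axis] - 1); idx_src[[axis]] <- 2:d[axis] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(1, -1))
    interior <- interior & shift_and(fg, ax, by)
  surf <- fg & !interior
  idx <- which(surf, arr.ind = TRUE)
  (idx - 0.5) * vs
}

# Sphericity classification rule: both criteria must hold.
classify_spherical <- function(axis_ratio, sphericity) {
  axis_ratio >= 0.7 && sphericity >= 0.95
}

#' 3D shape metrics of a binary pellet image
#'
#' Sphericity is the surface area of the volume-equivalent sphere divided
#' by the surface area of the convex hull of the foreground; the axis ratio
#' is the smallest over largest principal axis length from the second-moment
#' tensor of the foreground voxels. A pellet is classified as spherical when
#' the axis ratio is at least 0.7 and the sphericity at least 0.95.
#'
#' @param img binary [voxel_image()].
#' @param shells optional [shell_profile()] of the same pellet (for the
#'   border radius and total hyphal volume); computed from `img` if omitted.
#' @param n_dirs number of support directions for the convex hull.
#' @return object of class `shape_metrics_3d` with fields `sphericity`,
#'   `axis_ratio`, `is_spherical`, `total_hyphal_volume` (um^3),
#'   `border_radius` (um).
#' @export
shape_metrics_3d <- function(img, shells = NULL, n_dirs = 1500) {
  stopifnot(inherits(img, "voxel_image"))
  if (!is_binary_image(img)) stop_pellet("image must be binary")
  fg <- img$voxels > 0
  if (sum(fg) < 4) stop_pellet("need at least 4 foreground voxels for a hull")
  vs <- img$voxel_size
  if (is.null(shells)) shells <- shell_hyphal_fraction(img)

  vol <- sum(fg) * vs^3
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  centers <- surface_voxel_centers(fg, vs)
  hull <- convex_hull_3d(voxel_support_points(centers, vs / 2, n_dirs))
  sphericity <- 4 * pi * r_eq^2 / hull$area

  idx <- which(fg, arr.ind = TRUE)
  cov3 <- stats::cov(idx) + diag(1 / 12, 3)   # voxel self-moment
  ev <- eigen(cov3, symmetric = TRUE, only.values = TRUE)$values
  axis_ratio <- sqrt(min(ev) / max(ev))

  structure(list(sphericity = min(sphericity, 1),
                 axis_ratio = axis_ratio,
                 is_spherical = classify_spherical(axis_ratio, sphericity),
                 total_hyphal_volume = total_hyphal_volume(shells),
                 border_radius = border_from_fraction(shells)),
            class = "shape_metrics_3d")
}

#' @export
print.shape_metrics_3d <- function(x, ...) {
  cat(sprintf("Shape: sphericity %.3f, axis ratio %.3f -> %s\n",
              x$sphericity, x$axis_ratio,
              if (x$is_spherical) "spherical" else "nonspherical"))
  cat(sprintf("  border radius %.0f um, hyphal volume %.3g um^3\n",
              x$border_radius, x$total_hyphal_volume))
  invisible(x)
}

#' 2D binary mask of a projected pellet
#'
#' @param mask logical matrix (TRUE = pellet).
#' @param pixel_size pixel edge length, um.
#' @return object of class `mask2d`.
#' @export
mask2d <- function(mask, pixel_size = 1) {
  if (!is.matrix(mask)) stop_pellet("mask must be a matrix")
  structure(list(mask = mask > 0, pixel_size = pixel_size), class = "mask2d")
}

#' Euclidean shape descriptors of a 2D pellet mask
#'
#' Projected area, solidity (area over convex-hull area), maximum Feret
#' (caliper) diameter, aspect ratio of the moment-equivalent ellipse
#' (major/minor, >= 1) and the area-equivalent spherical diameter
#' `AESD = 2 sqrt(area/pi)`.
#'
#' @param m a [mask2d()].
#' @return object of class `descriptors_2d` with fields `area` (um^2),
#'   `solidity`, `feret_diameter` (um), `aspect_ratio`, `aesd` (um).
#' @export
descriptors_2d <- function(m) {
  stopifnot(inherits(m, "mask2d"))
  msk <- m$mask
  ps <- m$pixel_size
  n <- sum(msk)
  if (n == 0) stop_pellet("empty mask")
  area <- n * ps^2

  # boundary pixels carry all hull information
  pad <- matrix(FALSE, nrow(msk) + 2, ncol(msk) + 2)
  pad[2:(nrow(msk) + 1), 2:(ncol(msk) + 1)] <- msk
  inner <- pad[2:(nrow(msk) + 1), 2:(ncol(msk) + 1)] &
    pad[1:nrow(msk), 2:(ncol(msk) + 1)] & pad[3:(nrow(msk) + 2), 2:(ncol(msk) + 1)] &
    pad[2:(nrow(msk) + 1), 1:ncol(msk)] & pad[2:(nrow(msk) + 1), 3:(ncol(msk) + 2)]
  bidx <- which(msk & !inner, arr.ind = TRUE)
  corners <- rbind(
    (bidx - 1) * ps,
    cbind(bidx[, 1], bidx[, 2] - 1) * ps,
    cbind(bidx[, 1] - 1, bidx[, 2]) * ps,
    bidx * ps)
  hullidx <- grDevices::chull(corners)
  hv <- corners[hullidx, , drop = FALSE]
  hull_area <- abs(sum(hv[, 1] * c(hv[-1, 2], hv[1, 2]) -
                         c(hv[-1, 1], hv[1, 1]) * hv[, 2])) / 2
  feret <- sqrt(max(as.matrix(stats::dist(hv))^2))

  idx <- which(msk, arr.ind = TRUE)
  cov2 <- if (n > 1) stats::cov(idx) * (n - 1) / n else matrix(0, 2, 2)
  cov2 <- cov2 + diag(1 / 12, 2)
  ev <- eigen(cov2, symmetric = TRUE, only.values = TRUE)$values
  structure(list(area = area,
                 solidity = min(area / hull_area, 1),
                 feret_diameter = feret,
                 aspect_ratio = sqrt(max(ev) / min(ev)),
                 aesd = 2 * sqrt(area / pi)),
            class = "descriptors_2d")
}

#' Morphology number of a projected pellet
#'
#' Dimensionless roundness/smoothness descriptor
#' `MN = 2 sqrt(area * solidity / pi) / (feret * aspect_ratio)`;
#' equals 1 for a perfect circle and decreases for elongated or ragged
#' outlines.
#'
#' @param d a [descriptors_2d()] object.
#' @return morphology number in (0, 1\] for convex masks.
#' @export
morphology_number <- function(d) {
  stopifnot(inherits(d, "descriptors_2d"))
  if (d$feret_diameter <= 0 || d$aspect_ratio <= 0)
    stop_pellet("feret diameter and aspect ratio must be positive")
  2 * sqrt(d$area * d$solidity / pi) / (d$feret_diameter * d$aspect_ratio)
}
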