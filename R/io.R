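#' Read and write 3D voxel images as TIFF stacks
#'
#' One grayscale TIFF page per z slice. Writing scales binary images to
#' {0, 1} 8-bit; reading returns intensities in their native 0-1 range as
#' stored by the tiff package.
#'
#' @param img a [voxel_image()].
#' @param path file path of the multi-page TIFF.
#' @param voxel_size voxel edge length, um (metadata is not stored in the
#'   TIFF itself).
#' @return `read_pellet_tiff` returns a `voxel_image`.
#' @export
write_pellet_tiff <- function(img, path) {
  stopifnot(inherits(img, "voxel_image"))
  v <- img$voxels
  if (is.logical(v)) v <- v * 1
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
  slices <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_pellet_tiff
#' @export
read_pellet_tiff <- function(path, voxel_size = 1) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d <- dim(slices[[1]])
  arr <- array(0, c(d[1], d[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  voxel_image(arr, voxel_size)
}

#' Write a fit result or pellet record as JSON
#'
#' @param x a `fit_result` or `pellet_record`.
#' @param path file path.
#' @export
write_result_json <- function(x, path) {
  serialise <- function(obj) {
    if (inherits(obj, "pellet_record")) {
      list(pellet_id = obj$pellet_id, strain = obj$strain,
           is_spherical = obj$is_spherical,
           metrics = unclass(obj$metrics),
           shape = if (!is.null(obj$shape)) unclass(obj$shape),
           fit = serialise(obj$fit))
    } else if (inherits(obj, "fit_result")) {
      u <- unclass(obj)
      u$estimates <- as.list(u$estimates)
      u
    } else unclass(obj)
  }
  jsonlite::write_json(serialise(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
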