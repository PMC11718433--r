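# 3D convex hull by incremental insertion.
#
# Small self-contained quickhull-style implementation used for pellet
# sphericity (surface area of the convex hull of foreground voxel corners).
# Input sizes are kept modest upstream by support-point reduction, so a
# vectorised R implementation is entirely adequate.

# Quasi-uniform directions on the unit sphere (Fibonacci lattice).
fibonacci_directions <- function(k) {
  i <- seq_len(k) - 0.5
  z <- 1 - 2 * i / k
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Support points of a voxel set: for each direction, the corner of the
# voxel cube that maximises the dot product. The corner offset
# sign(u) * h is identical for all voxels of a direction, so the argmax
# over voxel centres plus that offset is the exact argmax over all corners.
# `centers` is an m x 3 matrix of voxel centres, `h` the half voxel edge.
voxel_support_points <- function(centers, h, n_dirs = 1500) {
  dirs <- fibonacci_directions(n_dirs)
  pts <- matrix(0, n_dirs, 3)
  chunk <- 200L
  for (s in seq(1, n_dirs, by = chunk)) {
    e <- min(s + chunk - 1L, n_dirs)
    d <- dirs[s:e, , drop = FALSE]
    scores <- centers %*% t(d)               # m x chunk
    idx <- max.col(t(scores), ties.method = "first")
    pts[s:e, ] <- centers[idx, , drop = FALSE] + sign(d) * h
  }
  unique(pts)
}

face_normals <- function(pts, faces) {
  a <- pts[faces[, 1], , drop = FALSE]
  b <- pts[faces[, 2], , drop = FALSE]
  c_ <- pts[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Convex hull of a 3D point set
#'
#' Incremental convex hull; returns the triangulated hull with its surface
#' area and enclosed volume.
#'
#' @param pts numeric matrix with 3 columns.
#' @return list with `faces` (m x 3 vertex indices into `pts`), `area`
#'   and `volume`.
#' @export
convex_hull_3d <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (ncol(pts) != 3) stop_pellet("points must have 3 columns")
  n <- nrow(pts)
  scale <- max(apply(pts, 2, function(x) diff(range(x))), 0)
  if (n < 4 || scale == 0) stop_pellet("convex hull needs >= 4 non-coplanar points")
  eps <- 1e-10 * scale

  # initial tetrahedron from extreme points
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  u <- pts[i2, ] - pts[i1, ]
  w <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(w[, 2] * u[3] - w[, 3] * u[2],
              w[, 3] * u[1] - w[, 1] * u[3],
              w[, 1] * u[2] - w[, 2] * u[1])
  i3 <- which.max(rowSums(cr^2))
  nrm <- c(u[2] * (pts[i3, 3] - pts[i1, 3]) - u[3] * (pts[i3, 2] - pts[i1, 2]),
           u[3] * (pts[i3, 1] - pts[i1, 1]) - u[1] * (pts[i3, 3] - pts[i1, 3]),
           u[1] * (pts[i3, 2] - pts[i1, 2]) - u[2] * (pts[i3, 1] - pts[i1, 1]))
  hvals <- w %*% nrm
  i4 <- which.max(abs(hvals))
  if (sqrt(sum(cr[i3, ]^2)) <= eps * scale || abs(hvals[i4]) <= eps * scale)
    stop_pellet("convex hull needs >= 4 non-coplanar points")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(faces) {
    nr <- face_normals(pts, faces)
    below <- rowSums(nr * (matrix(interior, nrow(faces), 3, byrow = TRUE) -
                             pts[faces[, 1], , drop = FALSE])) > 0
    faces[below, ] <- faces[below, c(1, 3, 2)]
    faces
  }
  faces <- orient(faces)

  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (ip in remaining) {
    nr <- face_normals(pts, faces)
    d <- rowSums(nr * (matrix(pts[ip, ], nrow(faces), 3, byrow = TRUE) -
                         pts[faces[, 1], , drop = FALSE]))
    # normalise by facet size so the visibility test is scale-free
    vis <- d > eps * pmax(sqrt(rowSums(nr^2)), eps)
    if (!any(vis)) next
    visf <- faces[vis, , drop = FALSE]
    edges <- rbind(visf[, c(1, 2)], visf[, c(2, 3)], visf[, c(3, 1)])
    keys <- paste(edges[, 1], edges[, 2])
    rkeys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(keys %in% rkeys), , drop = FALSE]
    newf <- cbind(horizon, ip)
    faces <- rbind(faces[!vis, , drop = FALSE], orient(newf))
  }

  nr <- face_normals(pts, faces)
  areas <- sqrt(rowSums(nr^2)) / 2
  vols <- rowSums((pts[faces[, 1], , drop = FALSE] -
                     matrix(interior, nrow(faces), 3, byrow = TRUE)) * nr) / 6
  list(faces = faces, area = sum(areas), volume = abs(sum(vols)))
}
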