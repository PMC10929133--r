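#' Principal axis of a binary mask by pixel-coordinate PCA
#'
#' Treats the set pixels as a scatter of (row, col) points, computes the
#' population covariance matrix (divide by N) of those coordinates, and takes
#' the eigenvector of the larger eigenvalue as the shape's long axis — the
#' tooth's longitudinal axis when applied to a whole-tooth mask. The
#' direction's sign is canonicalized to a non-negative row component (ties
#' broken toward a non-negative column component) so results are
#' deterministic across platforms.
#'
#' When the two eigenvalues are (nearly) equal the axis direction is
#' arbitrary — a disc has no long axis — and `degenerate` is set. Such teeth
#' are still measured downstream but carry a quality flag, since a
#' near-isotropic shape can yield an axis perpendicular to the anatomical one.
#'
#' @param mask Logical (or 0/1) matrix with at least 2 set pixels.
#' @return An object of class `principal_axis`: a list with `centroid`
#'   (`c(row, col)`), `direction` and `minor_direction` (unit 2-vectors),
#'   `eigenvalues` (`c(major, minor)`, pixel^2), and `degenerate` (logical,
#'   relative eigenvalue gap below 1e-6).
#' @export
principal_axis <- function(mask) {
  pts <- mask_points(mask)
  if (nrow(pts) < 2L) rlang::abort("`mask` must contain at least 2 set pixels.")
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2, centroid)
  covm <- crossprod(centered) / nrow(pts) # population (1/N) normalization
  eig <- eigen(covm, symmetric = TRUE)
  d <- eig$vectors[, 1]
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  m <- eig$vectors[, 2]
  if (m[1] < 0 || (m[1] == 0 && m[2] < 0)) m <- -m
  lam <- pmax(eig$values, 0)
  degenerate <- (lam[1] - lam[2]) / max(lam[1], 1e-12) < 1e-6
  structure(
    list(centroid = unname(centroid), direction = unname(d),
         minor_direction = unname(m),
         eigenvalues = unname(lam), degenerate = degenerate),
    class = "principal_axis"
  )
}

#' @export
print.principal_axis <- function(x, ...) {
  cat(sprintf(
    "<principal_axis> centroid (%.2f, %.2f), direction (%.4f, %.4f), eigenvalues (%.2f, %.2f)%s\n",
    x$centroid[1], x$centroid[2], x$direction[1], x$direction[2],
    x$eigenvalues[1], x$eigenvalues[2], if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

# (row, col) coordinates of set pixel centers, as a 2-column matrix.
mask_points <- function(mask) {
  if (!is.matrix(mask)) rlang::abort("`mask` must be a matrix.")
  storage.mode(mask) <- "logical"
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) rlang::abort("`mask` has no set pixels.")
  idx <- idx[, c("row", "col"), drop = FALSE]
  storage.mode(idx) <- "double"
  unname(idx)
}

#' PCA-aligned circumscribing ellipse of a binary mask
#'
#' The enclosing ellipse used to Euclideanize the tooth shape: centered at
#' the PCA centroid, oriented along the principal axis, with semi-axes
#' `sqrt(eigenvalue)` scaled by the maximum Mahalanobis radius over the set
#' pixels so that every pixel center lies inside or on the ellipse. This is
#' the PCA-attributed enclosing ellipse, not the minimum-area enclosing
#' ellipse; only the axis direction feeds the downstream measurement, the
#' ellipse itself is for visualization.
#'
#' @param mask Logical matrix with at least 3 non-collinear set pixels.
#' @return An object of class `tooth_ellipse`: list with `center`
#'   (`c(row, col)`), `semi_major`, `semi_minor` (pixels), `orientation`
#'   (radians of the major axis, measured from the +col axis toward +row).
#' @export
circumscribing_ellipse <- function(mask) {
  axis <- principal_axis(mask)
  lam <- axis$eigenvalues
  if (lam[2] <= 1e-12) {
    rlang::abort("Degenerate mask: set pixels are collinear; an enclosing ellipse needs 3 non-collinear pixels.")
  }
  pts <- mask_points(mask)
  centered <- sweep(pts, 2, axis$centroid)
  z1 <- centered %*% axis$direction
  z2 <- centered %*% axis$minor_direction
  scale <- sqrt(max(z1^2 / lam[1] + z2^2 / lam[2]))
  structure(
    list(center = axis$centroid,
         semi_major = scale * sqrt(lam[1]),
         semi_minor = scale * sqrt(lam[2]),
         orientation = atan2(axis$direction[1], axis$direction[2])),
    class = "tooth_ellipse"
  )
}

#' @export
print.tooth_ellipse <- function(x, ...) {
  cat(sprintf(
    "<tooth_ellipse> center (%.2f, %.2f), semi-axes (%.2f, %.2f) px, orientation %.2f rad\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor, x$orientation
  ))
  invisible(x)
}

#' Convex hull of a binary mask's pixel centers
#'
#' Returns the convex hull as an ordered polygon. The hull bridges gaps
#' between disconnected components — for a multi-rooted tooth it spans both
#' roots, which is what makes the axis-length measurement well defined there.
#' Vertices are ordered counter-clockwise in the (row, col) plane (treating
#' row as x and col as y) and collinear boundary points are dropped.
#'
#' @param mask Logical matrix with at least 1 set pixel.
#' @return An object of class `hull_polygon`: list with `vertices`, an
#'   n x 2 matrix of (row, col) points.
#' @export
convex_hull <- function(mask) {
  pts <- unique(mask_points(mask))
  hull_of_points(pts)
}

# Hull of an n x 2 (row, col) point matrix. grDevices::chull does the hull;
# this wrapper fixes orientation and strips collinear vertices so the
# convexity invariant (strictly positive cross products) holds.
hull_of_points <- function(pts, tol = 1e-9) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1L) {
    return(structure(list(vertices = pts), class = "hull_polygon"))
  }
  if (n == 2L) {
    return(structure(list(vertices = pts), class = "hull_polygon"))
  }
  idx <- grDevices::chull(pts[, 2], pts[, 1])
  v <- pts[idx, , drop = FALSE]
  if (nrow(v) >= 3L) {
    # signed area in the (row, col) plane; reverse to make it positive (CCW)
    r <- v[, 1]; c <- v[, 2]
    area2 <- sum(r * c[c(2:nrow(v), 1)] - r[c(2:nrow(v), 1)] * c)
    if (area2 < 0) v <- v[nrow(v):1, , drop = FALSE]
    v <- drop_collinear(v, tol)
  }
  structure(list(vertices = v), class = "hull_polygon")
}

drop_collinear <- function(v, tol = 1e-9) {
  repeat {
    n <- nrow(v)
    if (n < 3L) break
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      p <- v[if (i == 1L) n else i - 1L, ]
      q <- v[i, ]
      r <- v[if (i == n) 1L else i + 1L, ]
      cross <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
      if (abs(cross) <= tol) keep[i] <- FALSE
    }
    if (all(keep)) break
    v <- v[keep, , drop = FALSE]
  }
  v
}

#' @export
print.hull_polygon <- function(x, ...) {
  cat(sprintf("<hull_polygon> %d vertices\n", nrow(x$vertices)))
  invisible(x)
}

#' Length of a principal axis inside a convex hull
#'
#' Clips the infinite line through `axis$centroid` along `axis$direction`
#' against the hull's half-planes and returns the Euclidean length of the
#' single intersection segment (single by convexity), or 0 when the line
#' misses the hull. The line is anchored at the whole-tooth centroid and
#' treated as infinite before clipping, so lengths measured in different
#' region hulls of the same tooth are directly comparable.
#'
#' @param axis A [principal_axis()] (or any list with `centroid` and unit
#'   `direction`).
#' @param hull A [convex_hull()] polygon.
#' @return Length in pixels (>= 0).
#' @export
axis_length_in_hull <- function(axis, hull) {
  stopifnot(inherits(hull, "hull_polygon"))
  v <- hull$vertices
  p0 <- axis$centroid
  d <- axis$direction
  n <- nrow(v)
  tol <- 1e-9
  if (n == 1L) {
    # point hull: positive length impossible
    return(0)
  }
  if (n == 2L) {
    # segment hull: positive length only if the line contains the segment
    e <- v[2, ] - v[1, ]
    off <- v[1, ] - p0
    if (abs(e[1] * d[2] - e[2] * d[1]) <= tol && abs(off[1] * d[2] - off[2] * d[1]) <= tol) {
      return(sqrt(sum(e^2)))
    }
    return(0)
  }
  tmin <- -Inf
  tmax <- Inf
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1L else i + 1L, ]
    edge <- b - a
    # vertices are CCW in (row, col)-as-(x, y), so the inward normal is the
    # left normal of the edge
    normal <- c(-edge[2], edge[1])
    # interior: normal . (p - a) >= 0 for p on the line p0 + t d,
    # i.e. t * denom >= num
    denom <- sum(normal * d)
    num <- sum(normal * (a - p0))
    if (abs(denom) <= tol) {
      if (num > tol) return(0) # line parallel to and outside this half-plane
    } else {
      t_hit <- num / denom
      if (denom > 0) tmin <- max(tmin, t_hit) else tmax <- min(tmax, t_hit)
    }
  }
  max(0, tmax - tmin)
}
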