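# Independent geometric oracles, deliberately coded differently from the
# package internals: the package rasterizer uses even-odd ray crossing, the
# hull wraps grDevices::chull, and the axis length comes from half-plane
# clipping. The oracles below use convex sign tests, exhaustive triangle
# membership, and dense sampling instead.

# Inside-or-on test for a CONVEX polygon (vertices in consistent order):
# the point must be on the same side of (or on) every edge.
convex_contains <- function(vertices, row, col, tol = 1e-9) {
  n <- nrow(vertices)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (vertices[j, 1] - vertices[i, 1]) * (col - vertices[i, 2]) -
      (vertices[j, 2] - vertices[i, 2]) * (row - vertices[i, 1])
    if (cross > tol) {
      if (sgn < 0) return(FALSE)
      sgn <- 1
    } else if (cross < -tol) {
      if (sgn > 0) return(FALSE)
      sgn <- -1
    }
  }
  TRUE
}

# Brute-force rasterization of a convex polygon at integer pixel centers.
brute_rasterize_convex <- function(row, col, height, width) {
  v <- cbind(row, col)
  mask <- matrix(FALSE, height, width)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      mask[r, c] <- convex_contains(v, r, c)
    }
  }
  mask
}

# O(n^4) brute-force convex hull vertex set: a point is a hull vertex iff it
# is not inside (or on the boundary of) the triangle of any three other
# points, degenerate triangles included — so collinear mid-edge points are
# excluded, matching the package's collinear-dropping rule.
brute_hull_vertices <- function(pts, tol = 1e-9) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  in_triangle <- function(p, a, b, c) {
    # barycentric membership with tolerance; handles degenerate triangles
    # via the segment test below
    d <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    if (abs(d) < tol) {
      on_seg <- function(p, a, b) {
        cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
        abs(cr) < tol &&
          p[1] >= min(a[1], b[1]) - tol && p[1] <= max(a[1], b[1]) + tol &&
          p[2] >= min(a[2], b[2]) - tol && p[2] <= max(a[2], b[2]) + tol
      }
      return(on_seg(p, a, b) || on_seg(p, b, c) || on_seg(p, a, c))
    }
    l1 <- ((b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2])) / d
    l2 <- ((p[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (p[2] - a[2])) / d
    l1 >= -tol && l2 >= -tol && l1 + l2 <= 1 + tol
  }
  keep <- rep(TRUE, n)
  for (q in seq_len(n)) {
    others <- setdiff(seq_len(n), q)
    done <- FALSE
    for (i in others) {
      for (j in others[others > i]) {
        for (k in others[others > j]) {
          if (in_triangle(pts[q, ], pts[i, ], pts[j, ], pts[k, ])) {
            keep[q] <- FALSE
            done <- TRUE
            break
          }
        }
        if (done) break
      }
      if (done) break
    }
  }
  pts[keep, , drop = FALSE]
}

# Dense-sampling oracle for the length of a line inside a convex polygon:
# walk the line in steps of `step` px over a range covering the polygon and
# count sample points inside.
sample_line_length <- function(vertices, centroid, direction, step = 0.01) {
  reach <- max(sqrt(rowSums(sweep(vertices, 2, centroid)^2))) + 1
  t <- seq(-reach, reach, by = step)
  pts_r <- centroid[1] + t * direction[1]
  pts_c <- centroid[2] + t * direction[2]
  inside <- vapply(seq_along(t), function(i) {
    convex_contains(vertices, pts_r[i], pts_c[i])
  }, logical(1))
  sum(inside) * step
}

# Random convex polygon: points on a circle (always in convex position)
# pushed through a random affine stretch, which preserves convexity.
random_convex_polygon <- function(n_vertices, center = c(0, 0), radius = 20) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  v <- cbind(sin(ang), cos(ang))
  stretch <- diag(stats::runif(2, 0.4, 1))
  rot_ang <- stats::runif(1, 0, pi)
  rot <- matrix(c(cos(rot_ang), -sin(rot_ang), sin(rot_ang), cos(rot_ang)), 2, 2)
  v <- radius * v %*% stretch %*% rot
  v <- sweep(v, 2, -center)
  hull_of_points_oracle_order(v)
}

# Order points in convex position counter-clockwise about their centroid
# (no hull computation needed: the points are already in convex position).
hull_of_points_oracle_order <- function(v) {
  ctr <- colMeans(v)
  v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
}

# Set-pixel (row, col) coordinates, for feeding masks to the oracles.
mask_points_for_test <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  unname(cbind(as.numeric(idx[, 1]), as.numeric(idx[, 2])))
}

# A small L-shaped (concave union of rectangles) test mask.
l_shaped_mask <- function() {
  m <- matrix(FALSE, 30, 30)
  m[5:25, 5:10] <- TRUE
  m[20:25, 5:25] <- TRUE
  m
}
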