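# Planar geometry primitives for annotation polygons and polylines.
# All polygons are n x 2 matrices (columns x, y) of pixel coordinates,
# open (last vertex != first); closure is implicit. Coordinates are 0-based,
# origin top-left, x = column, y = row.

#' Signed and absolute polygon area (shoelace formula)
#'
#' Area is computed from the vertex coordinates directly (vector measurement),
#' not by pixel counting, so it is independent of rasterization resolution.
#'
#' @param poly numeric matrix with two columns (x, y); open polygon.
#' @param signed if `TRUE`, return the signed area (positive for
#'   counterclockwise vertex order in a y-down image frame the sign is
#'   flipped relative to the mathematical convention; callers should use
#'   `abs()` unless orientation matters).
#' @return area in squared coordinate units.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  poly <- as_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  a <- sum(x * yn - xn * y) / 2
  if (signed) a else abs(a)
}

#' Polygon centroid (area-weighted)
#'
#' @inheritParams polygon_area
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) {
    stop("degenerate (zero-area) polygon: centroid undefined")
  }
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Second central moments of the uniform lamina bounded by the polygon,
# via Green's-theorem line integrals. Returns c(mu20, mu02, mu11),
# normalized by area (i.e. the covariance matrix entries of the lamina).
polygon_central_moments <- function(poly) {
  poly <- as_polygon(poly)
  cen <- polygon_centroid(poly)
  x <- poly[, 1L] - cen[1L]; y <- poly[, 2L] - cen[2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  mu20 <- sum(cr * (x^2 + x * xn + xn^2)) / 12
  mu02 <- sum(cr * (y^2 + y * yn + yn^2)) / 12
  mu11 <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  c(mu20 = mu20 / a, mu02 = mu02 / a, mu11 = mu11 / a)
}

#' Polygon eccentricity from second central moments
#'
#' Eccentricity of the ellipse with the same second central moments as the
#' polygon's interior (the ellipse-of-inertia convention used by regionprops
#' style morphometry), e = sqrt(1 - (b/a)^2) with a >= b the semi-axes.
#' A circle gives 0; values approach 1 for elongated outlines.
#'
#' @inheritParams polygon_area
#' @return eccentricity in \[0, 1).
#' @export
polygon_eccentricity <- function(poly) {
  m <- polygon_central_moments(poly)
  tr <- m[1L] + m[2L]
  det <- m[1L] * m[2L] - m[3L]^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc  # eigenvalues of the covariance matrix
  l2 <- tr / 2 - disc
  if (l1 <= 0) stop("degenerate polygon: moments not positive")
  unname(sqrt(max(0, 1 - l2 / l1)))
}

# Arc length of an open polyline (n x 2 matrix).
polyline_length <- function(pts) {
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

# Minimum distance between the vertex sets of two polygons/polylines.
# Boundaries are assumed densely sampled, so the vertex-to-vertex minimum
# is the boundary gap at annotation resolution.
min_vertex_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  # |ai - bj|^2 = |ai|^2 + |bj|^2 - 2 ai.bj, vectorized over all pairs
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

# First intersection distance along ray origin + t*dir (t > 0) with the
# polygon boundary; NA when the ray never crosses.
ray_polygon_distance <- function(origin, dir, poly) {
  poly <- as_polygon(poly)
  p1 <- poly
  p2 <- poly[c(2:nrow(poly), 1L), , drop = FALSE]
  ex <- p2[, 1L] - p1[, 1L]; ey <- p2[, 2L] - p1[, 2L]
  qx <- p1[, 1L] - origin[1L]; qy <- p1[, 2L] - origin[2L]
  denom <- dir[1L] * ey - dir[2L] * ex
  ok <- abs(denom) > 1e-12
  t <- (qx * ey - qy * ex) / denom        # distance along the ray
  u <- (qx * dir[2L] - qy * dir[1L]) / denom  # position along the edge
  # u tolerance keeps rays that graze a vertex exactly (shared endpoint of
  # two edges); the duplicate hit has equal t, so min() is unaffected
  hit <- ok & t > 1e-9 & u >= -1e-9 & u <= 1 + 1e-9
  if (!any(hit)) return(NA_real_)
  min(t[hit])
}

# TRUE when the closed polygon self-intersects (non-adjacent edges cross).
polygon_self_intersects <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  idx <- c(seq_len(n), 1L)
  segs <- lapply(seq_len(n), function(i) rbind(poly[idx[i], ], poly[idx[i + 1L], ]))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(segs[[i]], segs[[j]])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(s1, s2) {
  d1 <- s1[2L, ] - s1[1L, ]; d2 <- s2[2L, ] - s2[1L, ]
  denom <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(denom) < 1e-12) return(FALSE)  # parallel: treat as non-crossing
  q <- s2[1L, ] - s1[1L, ]
  t <- (q[1L] * d2[2L] - q[2L] * d2[1L]) / denom
  u <- (q[1L] * d1[2L] - q[2L] * d1[1L]) / denom
  t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
}

# Which points (m x 2) fall inside the polygon. Thin wrapper so the
# point-in-polygon backend lives in one place.
points_in_polygon <- function(pts, poly) {
  poly <- as_polygon(poly)
  mgcv::in.out(rbind(poly, poly[1L, , drop = FALSE]), as.matrix(pts))
}

# Rasterize a polygon into a logical H x W mask: TRUE where the pixel
# center (x = col-1, y = row-1) is inside. Restricted to the bounding box.
polygon_mask <- function(poly, dim_hw) {
  poly <- as_polygon(poly)
  h <- dim_hw[1L]; w <- dim_hw[2L]
  mask <- matrix(FALSE, h, w)
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  cols <- max(1L, floor(xr[1L]) + 1L):min(w, ceiling(xr[2L]) + 1L)
  rows <- max(1L, floor(yr[1L]) + 1L):min(h, ceiling(yr[2L]) + 1L)
  if (!length(cols) || !length(rows)) return(mask)
  grid <- cbind(rep(cols - 1L, each = length(rows)), rep(rows - 1L, length(cols)))
  inside <- points_in_polygon(grid, poly)
  mask[cbind(rep(rows, length(cols)), rep(cols, each = length(rows)))] <- inside
  mask
}

# Binary dilation with a disc of radius r pixels.
dilate_mask <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  side <- 2L * as.integer(radius_px) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  out <- EBImage::dilate(mask * 1, brush)
  matrix(as.logical(out > 0), nrow(mask), ncol(mask))
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L) {
    stop("polygon must be an n x 2 matrix with n >= 3")
  }
  storage.mode(poly) <- "double"
  # drop duplicated closing vertex if present
  if (isTRUE(all.equal(poly[1L, ], poly[nrow(poly), ], check.attributes = FALSE))) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  poly
}

# Regular polygon approximation of an ellipse, n vertices, rotation theta.
ellipse_polygon <- function(cx, cy, a, b, theta = 0, n = 96L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(theta) - y * sin(theta),
        cy + x * sin(theta) + y * cos(theta))
}
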