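# Planar geometry primitives for layer contours.
#
# A "ring" is an n x 2 numeric matrix of (x, y) vertices in micrometres,
# implicitly closed (last vertex connects back to the first). A layer polygon
# is a list(outer = ring, holes = list(ring, ...)); containment follows the
# even-odd rule over all rings, with points exactly on a boundary counted as
# inside.

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param ring An n x 2 matrix of (x, y) vertices, implicitly closed.
#' @return Area in the square of the coordinate unit (always >= 0).
#' @keywords internal
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Area of a polygon with holes, in square micrometres
#' @param poly list(outer = ring, holes = list of rings)
#' @keywords internal
polygon_area_um2 <- function(poly) {
  a <- ring_area(poly$outer)
  if (length(poly$holes)) a <- a - sum(vapply(poly$holes, ring_area, 0))
  a
}

# Crossing-number test for many points against one ring, vectorised over
# points. Points lying on an edge (within eps) are flagged separately so the
# caller can apply the boundary-inclusive convention.
ring_crossings <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- integer(length(px))
  on_edge <- logical(length(px))
  for (i in seq_len(n)) {
    xa <- x1[i]; ya <- y1[i]; xb <- x2[i]; yb <- y2[i]
    # on-segment test: collinear and within bounding box
    cr <- (xb - xa) * (py - ya) - (yb - ya) * (px - xa)
    seg_len2 <- (xb - xa)^2 + (yb - ya)^2
    tol <- eps * max(1, sqrt(seg_len2))
    on <- abs(cr) <= tol &
      px >= pmin(xa, xb) - tol & px <= pmax(xa, xb) + tol &
      py >= pmin(ya, yb) - tol & py <= pmax(ya, yb) + tol
    on_edge <- on_edge | on
    # half-open rule on y avoids double counting at shared vertices
    crosses <- ((ya > py) != (yb > py))
    if (any(crosses)) {
      xi <- xa + (py - ya) / (yb - ya) * (xb - xa)
      inside <- inside + as.integer(crosses & (px < xi))
    }
  }
  list(crossings = inside, on_edge = on_edge)
}

#' Even-odd point-in-polygon test (boundary-inclusive)
#'
#' Containment uses the even-odd rule over the outer ring and all holes; a
#' point exactly on any ring boundary counts as inside. This is the
#' convention used for assigning particle centroids to layer contours.
#'
#' @param px,py Point coordinates (micrometres), vectorised.
#' @param poly list(outer = ring, holes = list of rings).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  rings <- c(list(poly$outer), poly$holes %||% list())
  total <- integer(length(px))
  on_any <- logical(length(px))
  for (r in rings) {
    cc <- ring_crossings(px, py, r)
    total <- total + cc$crossings
    on_any <- on_any | cc$on_edge
  }
  (total %% 2L == 1L) | on_any
}

# Segment-intersection based simplicity test. O(n^2); contour rings are a
# few hundred vertices at most.
segments_properly_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Is a ring simple (non-self-intersecting)?
#' @keywords internal
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (sharing a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_properly_intersect(ring[idx[i, 1], ], ring[idx[i, 2], ],
                                      ring[idx[j, 1], ], ring[idx[j, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Do two layer polygons overlap (share interior area)?
#'
#' Two polygons (with holes) overlap when a vertex of one lies strictly
#' inside the other, or when any two edges properly cross. Polygons that
#' merely share a boundary (adjacent annular layers) do not overlap, and a
#' polygon nested inside another's hole does not overlap.
#' @keywords internal
polygons_overlap <- function(a, b) {
  verts_b <- do.call(rbind, c(list(b$outer), b$holes))
  verts_a <- do.call(rbind, c(list(a$outer), a$holes))
  if (any(point_in_polygon(verts_b[, 1], verts_b[, 2], a) &
          !on_boundary_of(verts_b, a))) return(TRUE)
  if (any(point_in_polygon(verts_a[, 1], verts_a[, 2], b) &
          !on_boundary_of(verts_a, b))) return(TRUE)
  for (ra in c(list(a$outer), a$holes)) {
    for (rb in c(list(b$outer), b$holes)) {
      if (rings_properly_cross(ra, rb)) return(TRUE)
    }
  }
  FALSE
}

# Vectorised proper-intersection test between all edge pairs of two rings.
rings_properly_cross <- function(ra, rb) {
  na <- nrow(ra); nb <- nrow(rb)
  ax1 <- ra[, 1]; ay1 <- ra[, 2]
  ax2 <- c(ax1[-1], ax1[1]); ay2 <- c(ay1[-1], ay1[1])
  bx1 <- rb[, 1]; by1 <- rb[, 2]
  bx2 <- c(bx1[-1], bx1[1]); by2 <- c(by1[-1], by1[1])
  DXb <- matrix(bx2 - bx1, na, nb, byrow = TRUE)
  DYb <- matrix(by2 - by1, na, nb, byrow = TRUE)
  BX1 <- matrix(bx1, na, nb, byrow = TRUE)
  BY1 <- matrix(by1, na, nb, byrow = TRUE)
  BX2 <- matrix(bx2, na, nb, byrow = TRUE)
  BY2 <- matrix(by2, na, nb, byrow = TRUE)
  d1 <- DXb * (ay1 - BY1) - DYb * (ax1 - BX1)
  d2 <- DXb * (ay2 - BY1) - DYb * (ax2 - BX1)
  dxa <- ax2 - ax1; dya <- ay2 - ay1
  d3 <- dxa * (BY1 - ay1) - dya * (BX1 - ax1)
  d4 <- dxa * (BY2 - ay1) - dya * (BX2 - ax1)
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
        ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

on_boundary_of <- function(pts, poly) {
  out <- logical(nrow(pts))
  for (r in c(list(poly$outer), poly$holes %||% list())) {
    out <- out | ring_crossings(pts[, 1], pts[, 2], r)$on_edge
  }
  out
}

ring_centroidish <- function(ring) c(mean(ring[, 1]), mean(ring[, 2]))

#' Sample points uniformly inside a polygon (rejection from bounding box)
#' @keywords internal
sample_in_polygon <- function(n, poly) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  bb <- apply(poly$outer, 2, range)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(32L, 2L * (n - nrow(out)))
    px <- stats::runif(m, bb[1, 1], bb[2, 1])
    py <- stats::runif(m, bb[1, 2], bb[2, 2])
    keep <- point_in_polygon(px, py, poly)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Rasterise a polygon onto the pixel grid (scanline fill)
#'
#' Marks pixels whose centres fall inside the polygon (even-odd). Used for
#' rendering smooth tissue background; layer assignment itself never
#' rasterises.
#'
#' @param poly layer polygon in micrometres.
#' @param ny,nx image dimensions (rows = y, cols = x).
#' @param pixel_um pixel edge length.
#' @return Logical ny x nx matrix.
#' @keywords internal
rasterize_polygon <- function(poly, ny, nx, pixel_um) {
  mask <- matrix(FALSE, ny, nx)
  rings <- c(list(poly$outer), poly$holes %||% list())
  ys <- (seq_len(ny) - 0.5) * pixel_um
  xcent <- (seq_len(nx) - 0.5) * pixel_um
  for (i in seq_len(ny)) {
    y <- ys[i]
    xs <- numeric(0)
    for (r in rings) {
      x1 <- r[, 1]; y1 <- r[, 2]
      x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
      cr <- (y1 > y) != (y2 > y)
      if (any(cr)) xs <- c(xs, x1[cr] + (y - y1[cr]) / (y2[cr] - y1[cr]) * (x2[cr] - x1[cr]))
    }
    if (length(xs) < 2) next
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      mask[i, xcent > xs[k] & xcent < xs[k + 1]] <- TRUE
    }
  }
  mask
}

#' Build an elliptical ring polygon
#' @param a,b outer semi-axes (um); @param cx,cy centre; inner semi-axes
#'   `a_in`, `b_in` give the hole (omit for a filled ellipse).
#' @keywords internal
ellipse_ring <- function(a, b, cx = 0, cy = 0, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(th), cy + b * sin(th))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
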