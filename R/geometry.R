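# Planar polygon helpers used for cell-coverage weights. Polygons are
# two-column matrices of (lon, lat) vertices, not closed. Within a single
# grid cell (<= ~0.1 deg) the lon-lat plane is an adequate local chart, so
# coverage *fractions* computed in degree coordinates equal the geodesic
# fractions to first order; absolute areas always come from cell_area_km2().

# Signed shoelace area (degree^2); sign encodes orientation.
poly_area_signed <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

poly_area <- function(p) abs(poly_area_signed(p))

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle
# c(w, s, e, n). Exact for convex subjects; returns a vertex matrix (possibly
# with 0-2 rows when the intersection is empty or degenerate).
clip_poly_rect <- function(p, rect) {
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  ix <- function(a, b, t) a + (b - a) * t
  # vertical boundary at x = v, keep side given by cmp
  vert <- function(v, keep_ge) list(
    inside = if (keep_ge) function(q) q[1] >= v else function(q) q[1] <= v,
    intersect = function(a, b) {
      t <- (v - a[1]) / (b[1] - a[1])
      c(v, ix(a[2], b[2], t))
    })
  horiz <- function(v, keep_ge) list(
    inside = if (keep_ge) function(q) q[2] >= v else function(q) q[2] <= v,
    intersect = function(a, b) {
      t <- (v - a[2]) / (b[2] - a[2])
      c(ix(a[1], b[1], t), v)
    })
  edges <- list(vert(rect[["w"]], TRUE), vert(rect[["e"]], FALSE),
                horiz(rect[["s"]], TRUE), horiz(rect[["n"]], FALSE))
  out <- p
  for (e in edges) {
    out <- clip_half(out, e$inside, e$intersect)
    if (nrow(out) == 0) break
  }
  out
}

# Fraction of the rectangle rect covered by (convex) polygon p.
rect_cover_fraction <- function(p, rect) {
  a_rect <- (rect[["e"]] - rect[["w"]]) * (rect[["n"]] - rect[["s"]])
  if (a_rect <= 0) return(0)
  poly_area(clip_poly_rect(p, rect)) / a_rect
}

# Convex hull of points as a CCW vertex matrix.
convex_hull <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  h <- pts[idx, , drop = FALSE]
  if (nrow(h) >= 3 && poly_area_signed(h) < 0) h <- h[rev(seq_len(nrow(h))), ]
  h
}
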