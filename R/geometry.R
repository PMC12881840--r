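# Exact 2-D polygon predicates used by the patch sampler.
# Polygons are simple rings stored as n x 2 matrices (no closing vertex).
# All predicates treat polygons and squares as closed point sets.

.orient <- function(a, b, c) {
  # sign of the cross product (b-a) x (c-a): >0 left turn, <0 right, 0 collinear
  v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (v > 0) 1L else if (v < 0) -1L else 0L
}

.on_segment <- function(a, b, p) {
  # p collinear with segment ab assumed; is p within the bounding box of ab?
  min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
}

.seg_intersect <- function(a, b, c, d) {
  # closed-segment intersection test (includes endpoint touching)
  o1 <- .orient(a, b, c); o2 <- .orient(a, b, d)
  o3 <- .orient(c, d, a); o4 <- .orient(c, d, b)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && .on_segment(a, b, c)) ||
    (o2 == 0 && .on_segment(a, b, d)) ||
    (o3 == 0 && .on_segment(c, d, a)) ||
    (o4 == 0 && .on_segment(c, d, b))
}

.seg_cross_proper <- function(a, b, c, d) {
  # strict crossing: the segments intersect at a single interior point
  o1 <- .orient(a, b, c); o2 <- .orient(a, b, d)
  o3 <- .orient(c, d, a); o4 <- .orient(c, d, b)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

.poly_edges <- function(poly) {
  n <- nrow(poly)
  cbind(seq_len(n), c(seq_len(n)[-1], 1L))
}

.poly_self_intersects <- function(poly) {
  n <- nrow(poly)
  e <- .poly_edges(poly)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      # skip adjacent edges (they share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (.seg_intersect(poly[e[i, 1], ], poly[e[i, 2], ],
                         poly[e[j, 1], ], poly[e[j, 2], ])) return(TRUE)
    }
  }
  FALSE
}

.point_in_poly <- function(p, poly) {
  # even-odd rule; points on the boundary count as inside
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[j, ]
    if (.orient(a, b, p) == 0 && .on_segment(a, b, p)) return(TRUE)
    if ((a[2] > p[2]) != (b[2] > p[2])) {
      xint <- a[1] + (p[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

.square_corners <- function(x, y, s)
  rbind(c(x, y), c(x + s, y), c(x + s, y + s), c(x, y + s))

.square_in_poly <- function(x, y, s, poly) {
  # square fully contained in a simple polygon: all corners inside and no
  # square edge strictly crosses a polygon edge
  corners <- .square_corners(x, y, s)
  for (i in 1:4) if (!.point_in_poly(corners[i, ], poly)) return(FALSE)
  e <- .poly_edges(poly)
  sq_e <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  for (i in 1:4) {
    for (k in seq_len(nrow(e))) {
      if (.seg_cross_proper(corners[sq_e[i, 1], ], corners[sq_e[i, 2], ],
                            poly[e[k, 1], ], poly[e[k, 2], ])) return(FALSE)
    }
  }
  TRUE
}

.square_intersects_poly <- function(x, y, s, poly) {
  # closed square and closed polygon share at least one point
  corners <- .square_corners(x, y, s)
  in_sq <- function(p) x <= p[1] && p[1] <= x + s && y <= p[2] && p[2] <= y + s
  for (k in seq_len(nrow(poly))) if (in_sq(poly[k, ])) return(TRUE)
  for (i in 1:4) if (.point_in_poly(corners[i, ], poly)) return(TRUE)
  e <- .poly_edges(poly)
  sq_e <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  for (i in 1:4) {
    for (k in seq_len(nrow(e))) {
      if (.seg_intersect(corners[sq_e[i, 1], ], corners[sq_e[i, 2], ],
                         poly[e[k, 1], ], poly[e[k, 2], ])) return(TRUE)
    }
  }
  FALSE
}

.polys_bbox <- function(polys) {
  xs <- unlist(lapply(polys, function(p) p[, 1]))
  ys <- unlist(lapply(polys, function(p) p[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}
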