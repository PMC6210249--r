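#' @useDynLib greenexp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Planar geometry primitives
#'
#' Polygons are simple rings: numeric matrices with two columns (x, y in
#' meters), implicitly closed. The package works in a planar metric
#' coordinate system throughout; reprojecting geographic data is the
#' caller's job.
#'
#' @name geometry
#' @keywords internal
NULL

stopifnot_finite_xy <- function(x, what = "coordinates") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("non-finite %s", what), call. = FALSE)
  invisible(x)
}

#' Polygon area
#'
#' @param ring an n x 2 coordinate matrix (implicitly closed simple ring).
#' @return area in square meters.
#' @export
poly_area <- function(ring) {
  if (is.null(ring) || nrow(ring) == 0) return(0)
  stopifnot_finite_xy(ring)
  poly_area_cpp(ring)
}

#' Area of the union of a set of polygons
#'
#' Exact (up to floating point) union area by slab decomposition; polygons
#' may overlap arbitrarily.
#'
#' @param rings list of n x 2 coordinate matrices.
#' @return union area in square meters.
#' @export
union_area <- function(rings) {
  rings <- Filter(function(r) !is.null(r) && nrow(r) >= 3, rings)
  if (length(rings) == 0) return(0)
  union_area_cpp(rings)
}

#' Clip a polygon by a convex polygon
#'
#' Sutherland-Hodgman clipping. The clip ring must be convex and
#' counter-clockwise; the subject may be any simple ring.
#'
#' @param subject,clip n x 2 coordinate matrices.
#' @return the clipped ring (0 rows when the intersection is empty).
#' @export
clip_polygon <- function(subject, clip) {
  clip_convex_cpp(subject, clip)
}

#' Distance from a point to a polygon or polygon set
#'
#' Zero when the point lies inside; otherwise the Euclidean distance to the
#' nearest boundary.
#'
#' @param pt length-2 numeric (x, y).
#' @param ring an n x 2 ring.
#' @export
point_polygon_distance <- function(pt, ring) {
  stopifnot_finite_xy(pt, "point")
  point_poly_dist_cpp(pt[1], pt[2], ring)
}

#' @rdname point_polygon_distance
#' @param rings list of rings; the minimum distance over the set is returned.
#' @export
nearest_feature_distance <- function(pt, rings) {
  if (length(rings) == 0) stop("empty polygon set: nearest distance undefined", call. = FALSE)
  min(vapply(rings, function(r) point_polygon_distance(pt, r), numeric(1)))
}

ring_bbox <- function(ring) {
  c(min(ring[, 1]), min(ring[, 2]), max(ring[, 1]), max(ring[, 2]))
}

bbox_overlaps <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

ensure_ccw <- function(ring) {
  n <- nrow(ring)
  a <- sum(ring[, 1] * ring[c(2:n, 1), 2] - ring[c(2:n, 1), 1] * ring[, 2])
  if (a < 0) ring[n:1, , drop = FALSE] else ring
}

#' Buffer construction
#'
#' `disc_polygon` approximates a disc of the given radius by a regular
#' polygon (64 segments per full circle by default, keeping the area within
#' 0.5% of pi r^2). `capsule_polygon` buffers a single straight segment
#' (a rectangle with semicircular caps); `polyline_capsules` buffers each
#' edge of a polyline, returning one capsule per edge.
#'
#' @param center,p,q length-2 numerics (x, y in meters).
#' @param radius buffer radius in meters; must be positive.
#' @param n_segments segments per full circle (>= 8).
#' @return a ring (or list of rings for `polyline_capsules`).
#' @export
disc_polygon <- function(center, radius, n_segments = 64) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive", call. = FALSE)
  stopifnot_finite_xy(center, "center")
  th <- seq(0, 2 * pi, length.out = n_segments + 1)[-(n_segments + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' @rdname disc_polygon
#' @export
capsule_polygon <- function(p, q, radius, n_segments = 64) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive", call. = FALSE)
  stopifnot_finite_xy(c(p, q), "segment endpoints")
  d <- q - p
  len <- sqrt(sum(d^2))
  if (len < 1e-9) return(disc_polygon(p, radius, n_segments))
  u <- d / len
  nl <- c(-u[2], u[1]) # left normal
  half <- max(4L, as.integer(n_segments / 2))
  a0 <- atan2(nl[2], nl[1])
  # cap around q sweeping from +normal to -normal through +direction
  th_q <- seq(a0, a0 - pi, length.out = half + 1)
  cap_q <- cbind(q[1] + radius * cos(th_q), q[2] + radius * sin(th_q))
  th_p <- seq(a0 - pi, a0 - 2 * pi, length.out = half + 1)
  cap_p <- cbind(p[1] + radius * cos(th_p), p[2] + radius * sin(th_p))
  ring <- rbind(cap_q, cap_p[-1, , drop = FALSE])
  ring <- ring[-nrow(ring), , drop = FALSE]
  ensure_ccw(ring)
}

#' @rdname disc_polygon
#' @param coords polyline vertices, an m x 2 matrix (m >= 2).
#' @export
polyline_capsules <- function(coords, radius, n_segments = 64) {
  if (nrow(coords) < 2) stop("polyline needs at least 2 vertices", call. = FALSE)
  lapply(seq_len(nrow(coords) - 1), function(i) {
    capsule_polygon(coords[i, ], coords[i + 1, ], radius, n_segments)
  })
}

#' Axis-aligned rectangle ring
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds in meters.
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  if (xmax <= xmin || ymax <= ymin) stop("degenerate rectangle", call. = FALSE)
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# Area of intersection between a set of pairwise-disjoint polygons (a layer
# class) and one convex buffer ring. Disjointness lets intersection areas sum.
layer_convex_intersection_area <- function(polys, convex, poly_bboxes = NULL) {
  if (length(polys) == 0) return(0)
  cb <- ring_bbox(convex)
  total <- 0
  for (i in seq_along(polys)) {
    bb <- if (is.null(poly_bboxes)) ring_bbox(polys[[i]]) else poly_bboxes[i, ]
    if (!bbox_overlaps(bb, cb)) next
    piece <- clip_convex_cpp(polys[[i]], convex)
    if (nrow(piece) >= 3) total <- total + poly_area_cpp(piece)
  }
  total
}

# Area of intersection between a disjoint polygon layer and a union of convex
# rings (e.g. the merged travel buffer): sum over layer polygons of the union
# area of the per-capsule clipped pieces.
layer_capsules_intersection_area <- function(polys, capsules, poly_bboxes = NULL) {
  if (length(polys) == 0 || length(capsules) == 0) return(0)
  cap_bb <- t(vapply(capsules, ring_bbox, numeric(4)))
  total <- 0
  for (i in seq_along(polys)) {
    bb <- if (is.null(poly_bboxes)) ring_bbox(polys[[i]]) else poly_bboxes[i, ]
    hit <- which(cap_bb[, 1] <= bb[3] & bb[1] <= cap_bb[, 3] &
                 cap_bb[, 2] <= bb[4] & bb[2] <= cap_bb[, 4])
    if (length(hit) == 0) next
    pieces <- list()
    for (j in hit) {
      pc <- clip_convex_cpp(polys[[i]], capsules[[j]])
      if (nrow(pc) >= 3) pieces[[length(pieces) + 1]] <- pc
    }
    if (length(pieces) == 1) total <- total + poly_area_cpp(pieces[[1]])
    else if (length(pieces) > 1) total <- total + union_area_cpp(pieces)
  }
  total
}
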