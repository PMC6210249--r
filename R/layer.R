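#' Construct a greenspace layer
#'
#' A layer bundles three polygon classes in a planar metric CRS:
#' `vegetation` (for vegetation coverage), `pa_sites` (physical-activity
#' sites: parks, squares, outdoor playgrounds) and `greenspaces` (targets of
#' the nearest-greenspace accessibility indicator). The three classes are
#' independent; callers whose accessibility targets are the vegetated areas
#' themselves may simply pass the same polygons for both.
#'
#' Polygons within one class are expected to be pairwise disjoint (the
#' synthetic generator guarantees this); coverage computations rely on it to
#' sum per-polygon intersection areas.
#'
#' @param vegetation,pa_sites,greenspaces lists of ring matrices.
#' @return an object of class `greenspace_layer`.
#' @export
greenspace_layer <- function(vegetation = list(), pa_sites = list(),
                             greenspaces = list()) {
  chk <- function(polys, what) {
    for (i in seq_along(polys)) {
      p <- polys[[i]]
      if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p)))
        stop(sprintf("invalid polygon %d in %s", i, what), call. = FALSE)
      if (poly_area(p) <= 0)
        stop(sprintf("zero-area polygon %d in %s", i, what), call. = FALSE)
    }
    polys
  }
  structure(list(vegetation = chk(vegetation, "vegetation"),
                 pa_sites = chk(pa_sites, "pa_sites"),
                 greenspaces = chk(greenspaces, "greenspaces")),
            class = "greenspace_layer")
}

#' @export
print.greenspace_layer <- function(x, ...) {
  cat(sprintf("greenspace layer: %d vegetation, %d PA-site, %d greenspace polygons\n",
              length(x$vegetation), length(x$pa_sites), length(x$greenspaces)))
  invisible(x)
}

layer_class_area <- function(polys) {
  if (length(polys) == 0) return(0)
  sum(vapply(polys, poly_area, numeric(1)))
}

layer_bboxes <- function(polys) {
  if (length(polys) == 0) return(matrix(numeric(0), 0, 4))
  t(vapply(polys, ring_bbox, numeric(4)))
}
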