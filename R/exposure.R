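#' Time-weighted coverage of a polygon class over an activity space
#'
#' The daily exposure indicator behind both vegetation coverage and
#' physical-activity-site coverage: for stay buffers the per-buffer covered
#' fraction is weighted by the share of the day spent there,
#' sum_i (S_i / Sb1000) (t_i / 24), and the merged travel buffer adds one
#' term (S_t / Sb500) (tt / 24). S_i is the intersection area of the class
#' polygons with buffer i. Because the stay weights and the travel weight
#' partition the 24 h day, the result lies in [0, 1].
#'
#' @param space an `activity_space` from [delineate()].
#' @param polys list of class polygons (pairwise disjoint).
#' @return covered fraction in [0, 1].
#' @keywords internal
time_weighted_coverage <- function(space, polys) {
  bbs <- layer_bboxes(polys)
  total <- 0
  for (b in space$stay_buffers) {
    if (length(polys) > 0) {
      s <- layer_convex_intersection_area(polys, b$ring, bbs)
      total <- total + (s / b$area) * b$weight
    }
  }
  tr <- space$travel
  if (!is.null(tr) && length(polys) > 0 && tr$area > 0) {
    s <- layer_capsules_intersection_area(polys, tr$capsules, bbs)
    total <- total + (s / tr$area) * tr$weight
  }
  total
}

#' Greenspace exposure indicators
#'
#' `vegetation_coverage` and `pa_site_coverage` are the time-weighted
#' fractions of the activity-space buffers covered by vegetation and by
#' physical-activity sites. `accessibility` is the mean Euclidean distance
#' (meters) from each stay point to its nearest greenspace polygon (zero
#' when the stay lies inside one); travel segments do not enter, since the
#' average ranges over activity sites only.
#'
#' @param space an `activity_space`.
#' @param layer a `greenspace_layer`.
#' @return a fraction in [0, 1] (coverages) or a distance in meters.
#' @export
vegetation_coverage <- function(space, layer) {
  time_weighted_coverage(space, layer$vegetation)
}

#' @rdname vegetation_coverage
#' @export
pa_site_coverage <- function(space, layer) {
  time_weighted_coverage(space, layer$pa_sites)
}

#' @rdname vegetation_coverage
#' @param diary an `activity_diary` (accessibility needs stay locations, not
#'   buffers).
#' @param within_buffer_only restrict the nearest-greenspace search to
#'   polygons whose bounding box intersects the stay's 1000 m buffer. The
#'   default searches the whole layer: a greenspace just outside the buffer
#'   is still the nearest one. With the restriction active, stays with no
#'   greenspace in reach contribute `NA` and the mean is taken over the
#'   remaining stays (with a warning).
#' @param stay_radius buffer radius used by `within_buffer_only`.
#' @export
accessibility <- function(diary, layer, within_buffer_only = FALSE,
                          stay_radius = 1000) {
  if (length(layer$greenspaces) == 0)
    stop("greenspaces set is empty: accessibility undefined", call. = FALSE)
  if (nrow(diary$stays) < 1) stop("diary has no stay points", call. = FALSE)
  bbs <- layer_bboxes(layer$greenspaces)
  d <- vapply(seq_len(nrow(diary$stays)), function(i) {
    pt <- c(diary$stays$x[i], diary$stays$y[i])
    cand <- layer$greenspaces
    if (within_buffer_only) {
      bb <- c(pt[1] - stay_radius, pt[2] - stay_radius,
              pt[1] + stay_radius, pt[2] + stay_radius)
      keep <- bbs[, 1] <= bb[3] & bb[1] <= bbs[, 3] &
              bbs[, 2] <= bb[4] & bb[2] <= bbs[, 4]
      if (!any(keep)) return(NA_real_)
      cand <- cand[keep]
    }
    nearest_feature_distance(pt, cand)
  }, numeric(1))
  if (anyNA(d)) {
    warning("some stays have no greenspace within their buffer; averaged over the rest")
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
  }
  mean(d)
}

#' Bundle the three exposure indicators for one participant
#'
#' @param diary an `activity_diary`.
#' @param space the matching `activity_space`; computed from the diary when
#'   `NULL`.
#' @param layer a `greenspace_layer`.
#' @param ... passed to [delineate()] when `space` is `NULL`.
#' @return one-row data.frame with `participant_id`, `GE1` (vegetation
#'   coverage), `GE2` (PA-site coverage), `GE3` (accessibility, meters).
#' @export
exposure_profile <- function(diary, space = NULL, layer, ...) {
  if (is.null(space)) space <- delineate(diary, ...)
  data.frame(participant_id = diary$participant_id,
             GE1 = vegetation_coverage(space, layer),
             GE2 = pa_site_coverage(space, layer),
             GE3 = accessibility(diary, layer),
             stringsAsFactors = FALSE)
}

#' Exposure profiles for a whole cohort
#'
#' @param diaries list of `activity_diary` objects.
#' @param layer a `greenspace_layer`.
#' @param ... passed to [delineate()].
#' @return data.frame with one row per participant.
#' @export
exposure_table <- function(diaries, layer, ...) {
  do.call(rbind, lapply(diaries, function(d) {
    exposure_profile(d, space = NULL, layer = layer, ...)
  }))
}
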