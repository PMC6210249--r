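#' Build the buffer around one stay point
#'
#' A disc of the given radius (default 1000 m) centered on the stay
#' location, approximated by a 64-gon so its area stays within 0.5% of
#' pi r^2.
#'
#' @param stay one-row data.frame (or list) with `x`, `y`.
#' @param radius buffer radius in meters.
#' @param n_segments polygon resolution per full circle.
#' @return a ring matrix.
#' @export
build_stay_buffer <- function(stay, radius = 1000, n_segments = 64) {
  disc_polygon(c(stay$x, stay$y), radius, n_segments)
}

#' Build the merged travel-route buffer
#'
#' Every travel segment of the day is buffered at the given radius (default
#' 500 m) and the buffers are merged into a single travel buffer: the
#' exposure formula carries exactly one travel term, so all routes share one
#' time weight. Returns the list of capsule rings making up the buffer; its
#' area is the union area of the capsules.
#'
#' @param travels list of travel segments (see [activity_diary()]).
#' @param radius buffer radius in meters.
#' @param n_segments polygon resolution per full circle.
#' @return list with `capsules` (list of rings, possibly empty) and `area`.
#' @export
build_travel_buffer <- function(travels, radius = 500, n_segments = 64) {
  caps <- list()
  for (tr in travels) {
    caps <- c(caps, polyline_capsules(tr$polyline, radius, n_segments))
  }
  list(capsules = caps, area = union_area(caps))
}

#' Delineate a daily activity space
#'
#' The activity space is the set of time-weighted buffers of the diary: one
#' 1000 m disc per stay point with weight t_i / 24, and one merged 500 m
#' travel-route buffer with weight tt / 24. Stay buffers are deliberately
#' kept separate (not unioned): the exposure formula sums per-buffer terms
#' independently, so overlapping stay buffers contribute additively by
#' construction. The weights partition the day and always sum to 1.
#'
#' @param diary an `activity_diary` satisfying the 24 h budget.
#' @param stay_radius,travel_radius buffer radii in meters.
#' @param n_segments polygon resolution per full circle.
#' @return an object of class `activity_space` with `stay_buffers` (each a
#'   list of `ring`, `weight`, `area`, `activity_class`) and `travel`
#'   (`capsules`, `weight`, `area`; `NULL` when no time was spent
#'   traveling).
#' @export
delineate <- function(diary, stay_radius = 1000, travel_radius = 500,
                      n_segments = 64) {
  validate_diary(diary)
  stay_buffers <- lapply(seq_len(nrow(diary$stays)), function(i) {
    ring <- build_stay_buffer(diary$stays[i, ], stay_radius, n_segments)
    list(ring = ring, weight = diary$stays$duration[i] / 24,
         area = poly_area(ring),
         activity_class = diary$stays$activity_class[i])
  })
  tt <- travel_hours(diary)
  travel <- NULL
  if (tt > 0 && length(diary$travels) > 0) {
    tb <- build_travel_buffer(diary$travels, travel_radius, n_segments)
    travel <- list(capsules = tb$capsules, weight = tt / 24, area = tb$area)
  }
  structure(list(participant_id = diary$participant_id,
                 stay_buffers = stay_buffers, travel = travel),
            class = "activity_space")
}

#' @export
print.activity_space <- function(x, ...) {
  cat(sprintf("activity space [%s]: %d stay buffers, travel weight %.3f\n",
              x$participant_id, length(x$stay_buffers),
              if (is.null(x$travel)) 0 else x$travel$weight))
  invisible(x)
}

space_weights <- function(space) {
  w <- vapply(space$stay_buffers, function(b) b$weight, numeric(1))
  if (!is.null(space$travel)) w <- c(w, space$travel$weight)
  w
}
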