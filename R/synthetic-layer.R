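# Greenspace layers are generated as random axis-aligned rectangles thinned
# to remove within-class overlap: rectangle arithmetic keeps every area an
# exact quantity, which downstream coverage tests exploit. Rectangle centers
# follow a west-to-east density gradient so that a participant's home
# location induces correlated vegetation, PA-site and accessibility
# indicators -- the common factor the exposure measurement model rests on.

# x-coordinate with linearly increasing density across the window
grad_x <- function(n, xmin, xmax) {
  w <- xmax - xmin
  x <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      cand <- stats::runif(1, 0, w)
      if (stats::runif(1) < 0.25 + 0.75 * cand / w) { x[i] <- xmin + cand; break }
    }
  }
  x
}

place_rects <- function(target_area = NULL, n_target = NULL, side_meanlog,
                        side_sdlog, window, max_attempts = 2e5) {
  xmin <- window[1]; ymin <- window[2]; xmax <- window[3]; ymax <- window[4]
  rects <- matrix(numeric(0), 0, 4) # xmin ymin xmax ymax
  cum <- 0; attempts <- 0
  done <- function() {
    if (!is.null(target_area)) cum >= target_area else nrow(rects) >= n_target
  }
  while (!done()) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("could not place enough non-overlapping rectangles; window too small for the requested density",
           call. = FALSE)
    sx <- stats::rlnorm(1, side_meanlog, side_sdlog)
    sy <- stats::rlnorm(1, side_meanlog, side_sdlog)
    sx <- min(sx, (xmax - xmin) * 0.2); sy <- min(sy, (ymax - ymin) * 0.2)
    if (!is.null(target_area)) { # trim the closing rectangle to land exactly
      rem <- target_area - cum
      if (sx * sy > rem) sx <- max(rem / sy, 1e-6)
    }
    x0 <- grad_x(1, xmin, xmax - sx)
    y0 <- stats::runif(1, ymin, ymax - sy)
    if (nrow(rects) > 0 &&
        any(x0 < rects[, 3] & rects[, 1] < x0 + sx &
            y0 < rects[, 4] & rects[, 2] < y0 + sy)) next
    rects <- rbind(rects, c(x0, y0, x0 + sx, y0 + sy))
    cum <- cum + sx * sy
  }
  rects
}

rects_to_rings <- function(rects) {
  lapply(seq_len(nrow(rects)), function(i)
    rect_polygon(rects[i, 1], rects[i, 2], rects[i, 3], rects[i, 4]))
}

#' Generate a synthetic greenspace layer
#'
#' Fills the study window with non-overlapping (within class) random
#' rectangles: vegetation up to `greenspace_density` of the window area
#' (the closing rectangle is trimmed, so the total matches the target
#' essentially exactly), PA sites up to `pa_site_density`, and
#' `n_greenspaces` accessibility-target polygons. Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @return a [greenspace_layer()].
#' @export
generate_greenspace_layer <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  win <- config$study_window
  area <- (win[3] - win[1]) * (win[4] - win[2])

  veg <- if (config$greenspace_density > 0)
    rects_to_rings(place_rects(target_area = config$greenspace_density * area,
                               side_meanlog = log(250), side_sdlog = 0.35,
                               window = win))
  else list()
  pas <- if (config$pa_site_density > 0)
    rects_to_rings(place_rects(target_area = config$pa_site_density * area,
                               side_meanlog = log(120), side_sdlog = 0.30,
                               window = win))
  else list()
  grn <- if (config$n_greenspaces > 0)
    rects_to_rings(place_rects(n_target = config$n_greenspaces,
                               side_meanlog = log(300), side_sdlog = 0.30,
                               window = win))
  else list()
  layer <- greenspace_layer(vegetation = veg, pa_sites = pas, greenspaces = grn)
  attr(layer, "config") <- config
  layer
}
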