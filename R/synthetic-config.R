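#' Weekday time budget, hours per activity class
#'
#' Per-capita hours spent by activity class over a 24 h weekday, used as
#' the generator's default time budget (sums to exactly 24).
#' @export
TIME_BUDGET_HOURS <- c(residence = 13.20, work = 7.89, dining = 0.36,
                       shopping = 0.11, fitness = 0.09, entertainment = 0.10,
                       travel = 2.07, other = 0.18)

#' Cohort generation settings
#'
#' Bundles everything the synthetic generators need: cohort size, the mean
#' time budget per activity class (hours, must sum to 24), the planar study
#' window (meters), the fraction of the window covered by vegetation, the
#' mean number of diary items (stays plus travel segments) per participant,
#' and the RNG seed. `pa_site_density` and `n_greenspaces` size the two
#' remaining polygon classes.
#'
#' @param n_participants cohort size (>= 1).
#' @param time_budget_means named hours per class, summing to 24.
#' @param study_window `c(xmin, ymin, xmax, ymax)` in meters.
#' @param greenspace_density vegetation fraction of the window, in [0, 1].
#' @param pa_site_density PA-site fraction of the window.
#' @param n_greenspaces number of accessibility-target polygons.
#' @param mean_activities mean diary items per participant.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 1003,
                          time_budget_means = TIME_BUDGET_HOURS,
                          study_window = c(0, 0, 10000, 10000),
                          greenspace_density = 0.30,
                          pa_site_density = 0.04,
                          n_greenspaces = 40,
                          mean_activities = 14.4,
                          seed = 1L) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (abs(sum(time_budget_means) - 24) > 1e-9)
    stop("time_budget_means must sum to 24 h", call. = FALSE)
  need <- c("residence", "work", "travel")
  if (!all(need %in% names(time_budget_means)))
    stop("time budget needs at least residence, work and travel classes", call. = FALSE)
  if (study_window[3] <= study_window[1] || study_window[4] <= study_window[2])
    stop("degenerate study window", call. = FALSE)
  if (greenspace_density < 0 || greenspace_density > 1)
    stop("greenspace_density must lie in [0, 1]", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 time_budget_means = time_budget_means,
                 study_window = study_window,
                 greenspace_density = greenspace_density,
                 pa_site_density = pa_site_density,
                 n_greenspaces = as.integer(n_greenspaces),
                 mean_activities = mean_activities,
                 seed = as.integer(seed)),
            class = "cohort_config")
}
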