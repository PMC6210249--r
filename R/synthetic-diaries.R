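# Diary generation. Every participant-day is a closed tour
# home -> work -> minor stops -> home. Residence and work are always
# present; visits to the minor classes (dining, shopping, fitness,
# entertainment, other) arrive with Poisson counts calibrated so the mean
# number of diary items (stays + travel segments) matches the configured
# mean. Durations are drawn as mean-one lognormal perturbations of the
# class time budgets and then rescaled so each day sums to exactly 24 h.

MINOR_CLASSES <- c("dining", "shopping", "fitness", "entertainment", "other")

# mean-one lognormal noise
ln_noise <- function(n, sdlog = 0.25) stats::rlnorm(n, -sdlog^2 / 2, sdlog)

clip_to <- function(v, lo, hi) pmin(pmax(v, lo), hi)

make_travel_legs <- function(stops, total_hours) {
  n <- nrow(stops)
  legs <- vector("list", n)
  lens <- numeric(n)
  for (i in seq_len(n)) {
    a <- stops[i, ]; b <- stops[if (i == n) 1 else i + 1, ]
    nmid <- sample(0:3, 1)
    pts <- rbind(a, b)
    if (nmid > 0) {
      tfrac <- sort(stats::runif(nmid, 0.2, 0.8))
      mid <- cbind(a[1] + tfrac * (b[1] - a[1]) + stats::rnorm(nmid, 0, 150),
                   a[2] + tfrac * (b[2] - a[2]) + stats::rnorm(nmid, 0, 150))
      pts <- rbind(a, mid, b)
    }
    legs[[i]] <- pts
    lens[i] <- sum(sqrt(rowSums(diff(pts)^2))) + 50 # floor avoids 0-length legs
  }
  share <- lens / sum(lens)
  dur <- total_hours * share
  dur[n] <- total_hours - sum(dur[-n]) # close the budget exactly
  lapply(seq_len(n), function(i)
    list(polyline = unname(legs[[i]]), duration = dur[i], mode = "mixed"))
}

#' Generate a cohort of activity diaries
#'
#' Draws `n_participants` one-day diaries over the study window. Each diary
#' satisfies the 24 h budget exactly; across the cohort, the mean hours per
#' activity class converge to `time_budget_means` and the mean number of
#' recorded items to `mean_activities`. Deterministic given the config
#' seed.
#'
#' @param config a [cohort_config()].
#' @return list of [activity_diary()] objects.
#' @export
generate_diaries <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 2L)
  win <- config$study_window
  tb <- config$time_budget_means
  minor <- intersect(MINOR_CLASSES, names(tb))
  minor_budget <- tb[minor]
  # closed tour: items = 2 * n_stays, so E[n_stays] = mean_activities / 2
  lam_total <- max(config$mean_activities / 2 - 2, 0)
  lam <- if (sum(minor_budget) > 0) lam_total * minor_budget / sum(minor_budget)
         else stats::setNames(numeric(length(minor)), minor)

  margin <- min(500, (win[3] - win[1]) / 20)
  diaries <- vector("list", config$n_participants)
  for (pid in seq_len(config$n_participants)) {
    home <- c(stats::runif(1, win[1] + margin, win[3] - margin),
              stats::runif(1, win[2] + margin, win[4] - margin))
    work <- clip_to(home + stats::rnorm(2, 0, 1500),
                    win[c(1, 2)] + margin, win[c(3, 4)] - margin)
    cls <- c("residence", "work")
    xy <- rbind(home, work)
    w <- c(tb[["residence"]] * ln_noise(1), tb[["work"]] * ln_noise(1))
    for (mc in minor) {
      cnt <- stats::rpois(1, lam[[mc]])
      if (cnt == 0) next
      for (v in seq_len(cnt)) {
        loc <- clip_to(home + stats::rnorm(2, 0, 800),
                       win[c(1, 2)] + margin, win[c(3, 4)] - margin)
        xy <- rbind(xy, loc)
        cls <- c(cls, mc)
        w <- c(w, (minor_budget[[mc]] / lam[[mc]]) * ln_noise(1, 0.4))
      }
    }
    w_travel <- tb[["travel"]] * ln_noise(1)
    scale <- 24 / (sum(w) + w_travel)
    w <- w * scale; w_travel <- w_travel * scale

    # tour order: home first, return to home last; intermediates shuffled
    ord <- c(1, if (nrow(xy) > 2) sample(c(2, 3:nrow(xy))) else 2)
    stays <- data.frame(x = xy[, 1], y = xy[, 2], activity_class = cls,
                        duration = w, stringsAsFactors = FALSE)
    travels <- make_travel_legs(xy[ord, , drop = FALSE], w_travel)
    diaries[[pid]] <- activity_diary(sprintf("P%04d", pid), stays, travels)
  }
  diaries
}
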