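# Shared fixtures, all built in code.

# diary with explicit stay durations (hours) at given locations; remaining
# time becomes one straight travel leg unless travel_hours is 0
make_diary <- function(durations, locs = NULL, classes = NULL, travel_hours = 0,
                       id = "T1") {
  n <- length(durations)
  if (is.null(locs)) locs <- cbind(seq_len(n) * 5000, rep(0, n))
  if (is.null(classes)) classes <- rep("other", n)
  travels <- list()
  if (travel_hours > 0) {
    travels <- list(list(polyline = rbind(locs[1, ], locs[min(2, n), ] + c(1, 1)),
                         duration = travel_hours, mode = "walk"))
  }
  activity_diary(id,
                 data.frame(x = locs[, 1], y = locs[, 2],
                            activity_class = classes, duration = durations,
                            stringsAsFactors = FALSE),
                 travels)
}

# exact intersection area of two axis-aligned rectangles
rect_overlap_area <- function(a, b) {
  max(0, min(a[3], b[3]) - max(a[1], b[1])) *
    max(0, min(a[4], b[4]) - max(a[2], b[2]))
}

# layer with a single huge vegetation/PA/greenspace rectangle covering
# everything (saturation fixture)
saturating_layer <- function(extent = 1e6) {
  big <- list(rect_polygon(-extent, -extent, extent, extent))
  greenspace_layer(vegetation = big, pa_sites = big, greenspaces = big)
}

# two-latent toy model for algebraic checks
toy_model <- function() {
  sem_model("
    F =~ y1 + y2 + y3
    G =~ y4 + y5 + y6
    G ~ F
  ")
}

# deterministic sample covariance simulated from the default ground truth
truth_sample_cov <- function(n, seed) {
  sv <- generate_survey(default_ground_truth(), n = n, seed = seed)
  tab <- sem_input_table(sv)
  x <- as.matrix(tab[SEM_COLS])
  stats::cov(x)
}

SEM_COLS <- c("GE1", "GE2", "GE3", "PA1", "PA2", "PA3",
              "PH1", "PH2", "PH3", "MH1", "MH2", "MH3", "MH4", "MH5",
              "SH1", "SH2", "SH3", "SH4", "SH5")
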