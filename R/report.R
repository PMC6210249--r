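#' Cohort time-budget summary
#'
#' Per activity class: total hours across the cohort, per-capita hours
#' (total / N) and the percentage of the day (total / grand total), both
#' rounded half-up to 2 decimals. Works either from a list of diaries or
#' directly from printed class totals.
#'
#' @param diaries list of `activity_diary` objects.
#' @param totals alternatively, named vector of class total hours.
#' @param n cohort size (required with `totals`).
#' @return data.frame with `activity`, `total_hours`, `per_capita_hours`,
#'   `percent`, closing with a Total row.
#' @export
time_budget <- function(diaries = NULL, totals = NULL, n = NULL) {
  if (is.null(totals)) {
    if (is.null(diaries) || length(diaries) == 0)
      stop("empty cohort: no time budget", call. = FALSE)
    n <- length(diaries)
    acc <- numeric(0)
    for (d in diaries) {
      for (k in seq_len(nrow(d$stays))) {
        cl <- d$stays$activity_class[k]
        acc[cl] <- (if (is.na(acc[cl])) 0 else acc[cl]) + d$stays$duration[k]
      }
      th <- travel_hours(d)
      if (th > 0) acc["travel"] <- (if (is.na(acc["travel"])) 0 else acc["travel"]) + th
    }
    totals <- acc
  } else if (is.null(n)) stop("n is required with explicit totals", call. = FALSE)
  ord <- c(intersect(ACTIVITY_CLASSES, names(totals)),
           setdiff(names(totals), ACTIVITY_CLASSES))
  totals <- totals[ord]
  grand <- sum(totals)
  out <- data.frame(activity = c(names(totals), "total"),
                    total_hours = c(unname(totals), grand),
                    per_capita_hours = round_half_up(c(unname(totals), grand) / n, 2),
                    percent = round_half_up(100 * c(unname(totals), grand) / grand, 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mean number of recorded diary items per participant
#'
#' Items are stay points plus travel segments; reported to 1 decimal.
#'
#' @param diaries list of diaries, or `NULL` when passing counts directly.
#' @param n_items,n total item count and cohort size (alternative input).
#' @export
activities_per_participant <- function(diaries = NULL, n_items = NULL, n = NULL) {
  if (!is.null(diaries)) {
    n <- length(diaries)
    n_items <- sum(vapply(diaries, function(d)
      nrow(d$stays) + length(d$travels), numeric(1)))
  }
  if (is.null(n_items) || is.null(n) || n < 1)
    stop("need diaries or explicit counts", call. = FALSE)
  round_half_up(n_items / n, 1)
}

#' Run the full synthetic pipeline
#'
#' Generate a cohort (greenspace layer, diaries, survey), delineate
#' activity spaces, measure the three exposure indicators, score physical
#' activity and the health scales, check reliability, fit the structural
#' model by ML, prune nonsignificant paths and decompose effects. All
#' randomness derives from `config$seed`, so a seed fixes the report
#' exactly.
#'
#' @param config a [cohort_config()].
#' @param truth a [ground_truth()] driving the survey generator.
#' @param model a [sem_model()]; defaults to the exposure/activity/health
#'   structure.
#' @param alpha significance level for path pruning.
#' @param out_dir optional directory: writes `report.json`, the exposure
#'   and survey tables as CSV, and the layer classes as GeoJSON.
#' @return list with the intermediate tables, the `sem_fit`, indices,
#'   effect table and the serializable `report`.
#' @export
run_pipeline <- function(config = cohort_config(), truth = default_ground_truth(),
                         model = default_sem_model(), alpha = 0.05,
                         out_dir = NULL) {
  layer <- generate_greenspace_layer(config)
  diaries <- generate_diaries(config)
  exposures <- exposure_table(diaries, layer)
  survey <- generate_survey(truth, exposures = exposures, seed = config$seed)
  tab <- sem_input_table(survey)

  rel <- reliability_report(tab)
  S <- stats::cov(as.matrix(tab[model$obs]))
  fit <- ml_fit(S, nrow(tab), model)
  idx <- fit_indices(fit)
  fit <- prune_paths(fit, alpha)
  eff <- effect_decomposition(fit)

  tb <- time_budget(diaries)
  app <- activities_per_participant(diaries)

  report <- list(
    config = list(n_participants = config$n_participants,
                  greenspace_density = config$greenspace_density,
                  seed = config$seed),
    time_budget = tb,
    activities_per_participant = app,
    exposure_summary = lapply(exposures[c("GE1", "GE2", "GE3")], function(v)
      list(mean = mean(v), sd = stats::sd(v))),
    reliability = list(alpha_pooled = rel$alpha_pooled,
                       alpha_by_scale = as.list(rel$alpha_by_scale),
                       kmo = rel$kmo,
                       bartlett_p = rel$bartlett$p_value),
    pa_levels = as.list(table(classify_pa_level(tab$PA3)) / nrow(tab)),
    sem = list(F = fit$F, chisq = (fit$N - 1) * fit$F, df = fit$df,
               converged = fit$converged,
               indices = idx[c("CMIN_DF", "GFI", "RMR", "RMSEA",
                               "AGFI", "PNFI", "PCFI")],
               paths = fit$paths),
    effects = list(unrounded = as.data.frame(eff),
                   reported = as.data.frame(format_effect_table(eff))))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    utils::write.csv(exposures, file.path(out_dir, "exposures.csv"), row.names = FALSE)
    utils::write.csv(survey, file.path(out_dir, "survey.csv"), row.names = FALSE)
    write_layer_geojson(layer, out_dir)
  }
  invisible(list(layer = layer, diaries = diaries, exposures = exposures,
                 survey = survey, indicators = tab, reliability = rel,
                 fit = fit, indices = idx, effects = eff, report = report))
}
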