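test_that("half-up rounding follows the report convention", {
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-0.005, 2), -0.01)
  expect_equal(round_half_up(13.1964906, 2), 13.20)
  expect_equal(round_half_up(14.39581, 1), 14.4)
})

test_that("time budget closes arithmetically from diaries", {
  d1 <- make_diary(24, classes = "residence", id = "a")
  d2 <- make_diary(c(12, 9), classes = c("residence", "work"),
                   travel_hours = 3, id = "b")
  tb <- time_budget(list(d1, d2))
  expect_equal(tb$total_hours[tb$activity == "total"], 48)
  expect_equal(tb$per_capita_hours[tb$activity == "total"], 24)
  expect_equal(tb$percent[tb$activity == "total"], 100)
  expect_equal(tb$per_capita_hours[tb$activity == "residence"], 18)
  # percents sum to 100 within rounding; per-capita x N returns the totals
  body <- tb[tb$activity != "total", ]
  expect_lt(abs(sum(body$percent) - 100), 0.02)
  expect_equal(body$per_capita_hours * 2, body$total_hours, tolerance = 0.01)

  single <- time_budget(list(d1))
  expect_equal(single$percent[single$activity == "residence"], 100)
  expect_error(time_budget(list()), "empty")
})

test_that("activities per participant counts stays plus travel segments", {
  d <- make_diary(c(12, 9), classes = c("residence", "work"), travel_hours = 3)
  expect_equal(activities_per_participant(list(d)), 3) # 2 stays + 1 leg
  expect_equal(activities_per_participant(n_items = 5, n = 1), 5.0)
  expect_gte(activities_per_participant(list(d, d)), 1)
})

test_that("layer and activity-space GeoJSON round trips preserve geometry", {
  lay <- generate_greenspace_layer(
    cohort_config(greenspace_density = 0.05, n_greenspaces = 5, seed = 51))
  dir <- withr::local_tempdir()
  write_layer_geojson(lay, dir)
  back <- read_layer_geojson(dir)
  expect_length(back$vegetation, length(lay$vegetation))
  expect_equal(sum(vapply(back$vegetation, poly_area, numeric(1))),
               sum(vapply(lay$vegetation, poly_area, numeric(1))),
               tolerance = 1e-9)

  d <- make_diary(c(12, 9), classes = c("residence", "work"), travel_hours = 3)
  f <- file.path(dir, "space.geojson")
  write_activity_space_geojson(delineate(d), f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  kinds <- vapply(gj$features, function(x) x$properties$kind, character(1))
  expect_equal(sum(kinds == "stay"), 2)
  ws <- vapply(gj$features, function(x) x$properties$weight, numeric(1))
  expect_equal(sum(ws[kinds == "stay"]) + ws[kinds == "travel"][1], 1,
               tolerance = 1e-9)
})

test_that("cohort configuration reads back from YAML", {
  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_participants: 25", "greenspace_density: 0.2", "seed: 99",
               "study_window: [0, 0, 5000, 5000]"), cfgfile)
  cfg <- read_config(cfgfile)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_participants, 25L)
  expect_equal(cfg$study_window, c(0, 0, 5000, 5000))
  expect_equal(cfg$time_budget_means, TIME_BUDGET_HOURS)
})

test_that("the pipeline is deterministic per seed and ties the stages together", {
  cfg <- cohort_config(n_participants = 60, seed = 52)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, out_dir = dir1)
  r2 <- run_pipeline(cfg, out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "report.json")),
                   readLines(file.path(dir2, "report.json")))
  expect_equal(nrow(r1$exposures), 60)
  expect_true(all(c("GE1", "PA1", "MH3") %in% names(r1$indicators)))
  expect_s3_class(r1$effects, "effect_table")
  expect_equal(r1$effects$total, r1$effects$direct + r1$effects$indirect,
               tolerance = 1e-15)
})

test_that("the full synthetic pipeline recovers the injected structural paths", {
  res <- run_pipeline(cohort_config(n_participants = 2000, seed = 5))
  tr <- default_ground_truth()
  est <- res$fit$B_std
  for (nm in list(c("PA", "GE"), c("PH", "GE"), c("MH", "GE"), c("SH", "GE"),
                  c("PH", "PA"), c("MH", "PA"), c("SH", "PA")))
    expect_lt(abs(est[nm[1], nm[2]] - tr$paths[nm[1], nm[2]]), 0.08)
  expect_true(res$fit$converged)
  # measured exposure indicators share a common factor with expected signs
  ex <- res$exposures
  expect_gt(cor(ex$GE1, ex$GE2), 0.3)
  expect_lt(cor(ex$GE1, ex$GE3), -0.2)
})
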