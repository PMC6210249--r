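test_that("vegetation area tracks the requested density exactly per seed", {
  cfg <- cohort_config(n_participants = 1, greenspace_density = 0.30, seed = 21)
  lay <- generate_greenspace_layer(cfg)
  a <- sum(vapply(lay$vegetation, poly_area, numeric(1)))
  expect_gte(a, 28e6); expect_lte(a, 32e6)        # 10 km x 10 km window
  expect_lt(abs(a / 1e8 - 0.30), 0.02 * 0.30)     # within 2% of target

  zero <- generate_greenspace_layer(
    cohort_config(greenspace_density = 0, seed = 21))
  expect_length(zero$vegetation, 0)

  again <- generate_greenspace_layer(cfg)
  expect_identical(lay$vegetation, again$vegetation)
  expect_identical(lay$greenspaces, again$greenspaces)

  expect_error(cohort_config(study_window = c(0, 0, 0, 100)), "window")
})

test_that("layer polygons never overlap within a class", {
  lay <- generate_greenspace_layer(cohort_config(seed = 22))
  for (cls in c("vegetation", "pa_sites")) {
    bb <- t(vapply(lay[[cls]], function(r)
      c(min(r[, 1]), min(r[, 2]), max(r[, 1]), max(r[, 2])), numeric(4)))
    n <- nrow(bb)
    idx <- cbind(rep(1:n, each = 2), sample(n, 2 * n, replace = TRUE))
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    ov <- apply(idx, 1, function(k) {
      a <- bb[k[1], ]; b <- bb[k[2], ]
      max(0, min(a[3], b[3]) - max(a[1], b[1])) *
        max(0, min(a[4], b[4]) - max(a[2], b[2]))
    })
    expect_true(all(ov == 0))
  }
})

test_that("every generated diary closes its 24-hour budget to 1e-9", {
  diaries <- generate_diaries(cohort_config(n_participants = 200, seed = 23))
  res <- vapply(diaries, function(d)
    abs(24 - sum(d$stays$duration) - greenexp:::travel_hours(d)), numeric(1))
  expect_lt(max(res), 1e-9)
  # and the derived activity-space weights partition the day
  w <- vapply(diaries[1:20], function(d)
    sum(greenexp:::space_weights(delineate(d))), numeric(1))
  expect_equal(w, rep(1, 20), tolerance = 1e-12)
})

test_that("cohort time budgets converge to the configured per-capita hours", {
  cfg <- cohort_config(n_participants = 1003, seed = 24)
  diaries <- generate_diaries(cfg)
  tb <- time_budget(diaries)
  res <- tb$per_capita_hours[tb$activity == "residence"]
  expect_lt(abs(res - 13.20) / 13.20, 0.05)
  wk <- tb$per_capita_hours[tb$activity == "work"]
  expect_lt(abs(wk - 7.89) / 7.89, 0.05)
  tv <- tb$per_capita_hours[tb$activity == "travel"]
  expect_lt(abs(tv - 2.07) / 2.07, 0.05)
  app <- activities_per_participant(diaries)
  expect_lt(abs(app - 14.4), 1.0)

  d2 <- generate_diaries(cohort_config(n_participants = 2, seed = 25))
  expect_identical(generate_diaries(cohort_config(n_participants = 2, seed = 25)), d2)
})

test_that("ground truth validates its standardized structure", {
  tr <- default_ground_truth()
  Sg <- ground_truth_covariance(tr)
  expect_equal(Sg, t(Sg))
  expect_true(min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values) > 0)
  expect_equal(unname(diag(Sg)), rep(1, 19), tolerance = 1e-12)

  bad <- tr$loadings; bad["GE1"] <- 1.4
  expect_error(ground_truth(bad, tr$paths), "\\[-1, 1\\]")
  hot <- tr$paths; hot["PA", "GE"] <- 0.999; hot["MH", "PA"] <- 0.999
  hot["MH", "GE"] <- 0.999
  expect_error(ground_truth(tr$loadings, hot), "residual latent variance|positive definite")
})

test_that("a noiseless unit-loading indicator equals its discretized latent", {
  tr <- default_ground_truth()
  lo <- tr$loadings; lo["MH1"] <- 1
  ns <- sqrt(1 - lo^2); ns["MH1"] <- 0
  tr1 <- ground_truth(lo, tr$paths, tr$error_correlations, noise_sd = ns)
  sv <- generate_survey(tr1, n = 400, seed = 31)
  eta <- attr(sv, "latents")
  want <- as.integer(cut(eta[, "MH"],
                         c(-Inf, qnorm(c(0.2, 0.4, 0.6, 0.8)), Inf)))
  expect_equal(sv$MH1, want)
})

test_that("null structural paths leave indicator blocks uncorrelated", {
  tr <- default_ground_truth()
  none <- ground_truth(tr$loadings, matrix(0, 5, 5), tr$error_correlations[1])
  sv <- generate_survey(none, n = 4000, seed = 32)
  tab <- sem_input_table(sv)
  for (pair in list(c("GE1", "MH1"), c("GE2", "PA1"), c("PA3", "SH1"),
                    c("PH2", "SH3")))
    expect_lt(abs(cor(tab[[pair[1]]], tab[[pair[2]]])), 0.05)
})

test_that("sample covariance approaches the implied covariance as n grows", {
  tr <- default_ground_truth()
  Sg <- ground_truth_covariance(tr)
  cont <- c("GE1", "GE2", "GE3", "PA1", "PA3") # continuous indicators
  dist_at <- function(n) {
    tab <- sem_input_table(generate_survey(tr, n = n, seed = 33))
    norm(cor(as.matrix(tab[cont])) - Sg[cont, cont], type = "F")
  }
  d500 <- dist_at(500); d5000 <- dist_at(5000)
  expect_lt(d5000, d500)
  # Likert items converge too, up to the mild discretization attenuation
  tab <- sem_input_table(generate_survey(tr, n = 5000, seed = 34))
  rr <- cor(as.matrix(tab[c("MH1", "MH2", "MH3")]))
  expect_lt(max(abs(rr - Sg[c("MH1", "MH2", "MH3"), c("MH1", "MH2", "MH3")])),
            0.08)
})

test_that("simulated PA logs recover their duration and MET targets exactly", {
  sv <- generate_survey(default_ground_truth(), n = 500, seed = 35)
  expect_true(all(sv$walk_min >= 0 & sv$moderate_min >= 0 & sv$vigorous_min >= 0))
  pa <- score_pa_log(sv[c("participant_id", "walk_min", "moderate_min",
                          "vigorous_min", "sessions")])
  expect_equal(pa$PA3,
               met_minutes(sv$walk_min, sv$moderate_min, sv$vigorous_min))
  # volume is consistent with its duration bounds
  expect_true(all(pa$PA3 >= 3.5 * pa$PA1 - 1e-9))
  expect_true(all(pa$PA3 <= 8.0 * pa$PA1 + 1e-9))
  expect_gt(cor(pa$PA1, pa$PA3), 0.5) # both driven by the PA latent
})
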