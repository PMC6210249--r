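test_that("ML recovers the generating parameters at n = 2000", {
  tr <- default_ground_truth()
  S <- truth_sample_cov(2000, seed = 41)
  fit <- ml_fit(S, 2000, default_sem_model())
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-6)

  for (nm in list(c("PA", "GE"), c("PH", "GE"), c("MH", "GE"), c("SH", "GE"),
                  c("PH", "PA"), c("MH", "PA"), c("SH", "PA")))
    expect_lt(abs(fit$B_std[nm[1], nm[2]] - tr$paths[nm[1], nm[2]]), 0.08)

  # strong standardized loadings come back too (continuous indicators)
  est <- fit$estimates
  lam <- setNames(est$std[est$type == "loading"], est$label[est$type == "loading"])
  expect_lt(abs(lam[["GE=~GE2"]] - 0.87), 0.08)
  expect_lt(abs(lam[["PA=~PA3"]] - 0.82), 0.08)
})

test_that("rescaling an indicator leaves F, indices and standardized estimates unchanged", {
  S <- truth_sample_cov(600, seed = 42)
  mod <- default_sem_model()
  f1 <- ml_fit(S, 600, mod)
  S2 <- S
  S2["GE1", ] <- S2["GE1", ] * 1000; S2[, "GE1"] <- S2[, "GE1"] * 1000
  f2 <- ml_fit(S2, 600, mod)
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
  expect_equal(f1$estimates$std, f2$estimates$std, tolerance = 1e-6)
  i1 <- fit_indices(f1); i2 <- fit_indices(f2)
  for (k in c("CMIN_DF", "GFI", "RMR", "RMSEA", "AGFI", "PNFI", "PCFI"))
    expect_equal(i1[[k]], i2[[k]], tolerance = 1e-8)
  # unstandardized loading of the rescaled indicator scales with it
  l1 <- f1$estimates$est[f1$estimates$label == "GE=~GE2"]
  l2 <- f2$estimates$est[f2$estimates$label == "GE=~GE2"]
  expect_equal(l2, l1 / 1000, tolerance = 1e-6) # anchor GE1 grew by 1000
})

test_that("a perfectly fitting overidentified model hits the exact-fit limits", {
  Sg <- ground_truth_covariance(default_ground_truth())
  fit <- ml_fit(Sg, 1000, default_sem_model())
  expect_lt(fit$F, 1e-10)
  idx <- fit_indices(fit)
  expect_equal(idx$CMIN, 0, tolerance = 1e-6)
  expect_equal(idx$RMR, 0, tolerance = 1e-6)
  expect_equal(idx$RMSEA, 0)
  expect_equal(idx$GFI, 1, tolerance = 1e-9)
  expect_equal(idx$CFI, 1)
})

test_that("degenerate inputs are rejected with data errors", {
  mod <- default_sem_model()
  Sg <- ground_truth_covariance(default_ground_truth())
  bad <- Sg; bad[1, 1] <- -1
  expect_error(ml_fit(bad, 1000, mod), "positive definite")
  expect_error(ml_fit(Sg, 10, mod), "exceed")
  expect_error(ml_fit(unname(Sg), 1000, mod), "dimnames")
})

test_that("estimates and all indices agree with the independent reference fitter", {
  sv <- generate_survey(default_ground_truth(), n = 600, seed = 11)
  tab <- sem_input_table(sv)
  x <- scale(as.matrix(tab[SEM_COLS])) # unit scales: absolute 1e-3 comparable
  S <- cov(x)
  mod <- default_sem_model()
  fit <- ml_fit(S, 600, mod)
  idx <- fit_indices(fit)

  job <- list(S = unname(S), obs = colnames(S), N = 600,
              model = list(
                latents = mod$latents, indicators = mod$indicators,
                paths = list(c("PA", "GE"), c("PH", "GE"), c("PH", "PA"),
                             c("MH", "GE"), c("MH", "PA"), c("SH", "GE"),
                             c("SH", "PA")),
                error_covs = list(c("GE3", "PA2"), c("PA2", "PH3"))))
  jin <- withr::local_tempfile(fileext = ".json")
  jout <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(job, jin, auto_unbox = TRUE, digits = NA)
  script <- system.file("reference", "sem_ml_reference.py", package = "greenexp")
  status <- system2("python", c(script, jin, jout))
  expect_equal(status, 0)
  ref <- jsonlite::read_json(jout, simplifyVector = TRUE)

  expect_equal(fit$F, ref$F, tolerance = 1e-6)
  est <- setNames(fit$estimates$est, fit$estimates$label)
  common <- intersect(names(est), names(ref$estimates))
  expect_equal(length(common), nrow(fit$estimates))
  expect_lt(max(abs(est[common] - unlist(ref$estimates[common]))), 1e-3)
  for (k in c("CMIN_DF", "GFI", "RMR", "RMSEA", "AGFI", "PNFI", "PCFI"))
    expect_lt(abs(idx[[k]] - ref$indices[[k]]), 1e-3)
})
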