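test_that("MET-minutes follow the 3.5 / 4.0 / 8.0 weighting", {
  expect_equal(met_minutes(0, 0, 0), 0)
  expect_equal(met_minutes(60, 30, 15), 450)   # 210 + 120 + 120
  expect_equal(met_minutes(100, 0, 0), 350)
  expect_equal(met_minutes(0, 0, 100), 800)
  expect_error(met_minutes(-1, 0, 0), "nonnegative")

  set.seed(1) # linearity in each argument
  a <- runif(3, 0, 200); b <- runif(3, 0, 200)
  expect_equal(met_minutes(a[1] + b[1], a[2] + b[2], a[3] + b[3]),
               met_minutes(a[1], a[2], a[3]) + met_minutes(b[1], b[2], b[3]))
})

test_that("activity levels cut at 600 and 1500 with boundaries in the middle class", {
  expect_equal(as.character(classify_pa_level(c(0, 599.9, 600, 1000, 1500, 1500.1, 2000))),
               c("low", "low", "intermediate", "intermediate", "intermediate",
                 "high", "high"))
  expect_error(classify_pa_level(-5), "nonnegative")
  # monotone: sorted MET input gives non-decreasing level codes
  set.seed(2)
  m <- sort(runif(200, 0, 3000))
  expect_true(all(diff(as.integer(classify_pa_level(m))) >= 0))
})

test_that("scored PA logs carry duration, summed frequency, and MET volume", {
  log <- data.frame(participant_id = c("a", "b"),
                    walk_min = c(60, 0), moderate_min = c(30, 0),
                    vigorous_min = c(15, 200), sessions = c(5, 3))
  pa <- score_pa_log(log)
  expect_equal(pa$PA1, c(105, 200))
  expect_equal(pa$PA2, c(5, 3))
  expect_equal(pa$PA3, c(450, 1600))
  expect_equal(as.character(pa$level), c("low", "high"))
})

test_that("scale scoring validates the Likert range and reverse-codes bodily pain", {
  base <- as.data.frame(as.list(stats::setNames(rep(3L, 13),
    c(paste0("PH", 1:3), paste0("MH", 1:5), paste0("SH", 1:5)))))
  sc <- scale_scores(base)
  expect_equal(unlist(sc$scale_means[1, ]), c(ph = 3, mh = 3, sh = 3))

  hi <- base; hi[paste0("MH", 1:5)] <- 5L
  expect_equal(scale_scores(hi)$scale_means$mh, 5)

  rv <- base; rv$PH1 <- 1L # severe pain -> reversed to 5
  out <- scale_scores(rv)
  expect_equal(out$items$PH1, 5L)
  expect_equal(out$scale_means$ph, (5 + 3 + 3) / 3)

  bad <- base; bad$SH2 <- 7L
  expect_error(scale_scores(bad), "SH2")
})

test_that("Cronbach's alpha matches closed forms and behaves under correlation", {
  set.seed(3)
  x <- rnorm(200)
  dup <- cbind(x, x, x, x)
  expect_equal(cronbach_alpha(dup), 1)

  ind <- matrix(rnorm(10000 * 6), ncol = 6)
  expect_lt(abs(cronbach_alpha(ind)), 0.05)

  # two items: alpha = 2 (1 - (v1 + v2) / var(total)), checked by hand
  y <- cbind(rnorm(500), rnorm(500))
  y[, 2] <- 0.6 * y[, 1] + sqrt(1 - 0.36) * y[, 2]
  v <- apply(y, 2, var); vt <- var(y[, 1] + y[, 2])
  expect_equal(cronbach_alpha(y), 2 * (1 - (v[1] + v[2]) / vt), tolerance = 1e-12)

  # alpha grows with inter-item correlation, base noise held fixed
  set.seed(4)
  base <- matrix(rnorm(2000 * 4), ncol = 4); f <- rnorm(2000)
  alphas <- vapply(c(0.2, 0.5, 0.8), function(lam)
    cronbach_alpha(lam * f + sqrt(1 - lam^2) * base), numeric(1))
  expect_true(all(diff(alphas) > 0))

  expect_error(cronbach_alpha(matrix(1, 10, 3)), "variance")
  expect_error(cronbach_alpha(matrix(rnorm(4), 2, 2)), "observations")
})

test_that("KMO separates factorable from independent item sets", {
  set.seed(5)
  f <- rnorm(5000)
  fac <- 0.8 * f + sqrt(1 - 0.64) * matrix(rnorm(5000 * 6), ncol = 6)
  expect_gt(kmo(fac), 0.7)

  ind <- matrix(rnorm(5000 * 6), ncol = 6)
  expect_lt(abs(kmo(ind) - 0.5), 0.05)
  expect_gte(kmo(fac), 0); expect_lte(kmo(fac), 1)

  sing <- cbind(f, f, rnorm(5000))
  expect_error(kmo(sing), "singular")

  bt <- bartlett_sphericity(fac)
  expect_lt(bt$p_value, 1e-10)
  expect_equal(bt$df, 15)
})

test_that("the pooled reliability report covers alpha, per-scale alpha and KMO", {
  sv <- generate_survey(default_ground_truth(), n = 800, seed = 9)
  tab <- sem_input_table(sv)
  rep <- reliability_report(tab)
  expect_true(rep$alpha_pooled > 0.5 && rep$alpha_pooled < 1)
  expect_length(rep$alpha_by_scale, 3)
  expect_true(all(rep$alpha_by_scale > 0.4))
  expect_gt(rep$kmo, 0.6)
  expect_lt(rep$bartlett$p_value, 1e-10)
})
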