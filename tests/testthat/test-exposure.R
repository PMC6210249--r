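test_that("coverage saturates at 1 and vanishes at 0", {
  d <- make_diary(c(12, 9), classes = c("residence", "work"), travel_hours = 3)
  sp <- delineate(d)
  lay <- saturating_layer()
  expect_equal(vegetation_coverage(sp, lay), 1, tolerance = 1e-9)
  expect_equal(pa_site_coverage(sp, lay), 1, tolerance = 1e-9)
  empty <- greenspace_layer(greenspaces = lay$greenspaces)
  expect_equal(vegetation_coverage(sp, empty), 0)
  expect_equal(pa_site_coverage(sp, empty), 0)
})

test_that("coverage is the time-weighted mean of per-buffer fractions", {
  # two stays, 12 h each, far apart; vegetation fills buffer 1 entirely and
  # misses buffer 2 -> fractions 1 and 0, time-weighted mean 0.5
  d <- make_diary(c(12, 12), locs = rbind(c(0, 0), c(50000, 0)))
  sp <- delineate(d)
  lay <- greenspace_layer(vegetation = list(rect_polygon(-2000, -2000, 2000, 2000)))
  expect_equal(vegetation_coverage(sp, lay), 0.5, tolerance = 1e-9)

  # known interior rectangles: fractions a1/Sb, a2/Sb with exact areas
  v1 <- rect_polygon(-400, -400, 400, 400)       # inside buffer 1
  v2 <- rect_polygon(49900, -100, 50100, 100)    # inside buffer 2
  lay2 <- greenspace_layer(vegetation = list(v1, v2))
  sb <- sp$stay_buffers[[1]]$area
  want <- 0.5 * (800 * 800 / sb) + 0.5 * (200 * 200 / sb)
  expect_equal(vegetation_coverage(sp, lay2), want, tolerance = 1e-9)

  # single 24 h stay with a 5% PA-site fraction
  d1 <- make_diary(24, locs = cbind(0, 0))
  sp1 <- delineate(d1)
  site <- rect_polygon(-200, -196.3495, 200, 196.3495) # ~0.05 of pi r^2
  lay3 <- greenspace_layer(pa_sites = list(site))
  f <- poly_area(site) / sp1$stay_buffers[[1]]$area
  expect_equal(pa_site_coverage(sp1, lay3), f, tolerance = 1e-12)
})

test_that("the travel term weighs the merged route buffer by tt/24", {
  # one stay far away from a straight route; vegetation covers the whole
  # route corridor, so coverage = tt / 24 exactly
  stays <- data.frame(x = 1e6, y = 1e6, activity_class = "residence",
                      duration = 20, stringsAsFactors = FALSE)
  trav <- list(list(polyline = rbind(c(0, 0), c(2000, 0)), duration = 4))
  d <- activity_diary("T2", stays, trav)
  sp <- delineate(d)
  lay <- greenspace_layer(vegetation = list(rect_polygon(-1000, -1000, 3000, 1000)))
  expect_equal(vegetation_coverage(sp, lay), 4 / 24, tolerance = 1e-9)
})

test_that("coverage equals the rectangle-arithmetic oracle on interior fixtures", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    durs <- runif(k, 2, 10); durs <- durs * 24 / sum(durs)
    locs <- cbind(seq_len(k) * 30000, rep(0, k))
    d <- make_diary(durs, locs = locs)
    sp <- delineate(d)
    polys <- list(); want <- 0
    sb <- sp$stay_buffers[[1]]$area
    for (i in seq_len(k)) { # rectangles strictly inside buffer i
      m <- sample(0:2, 1)
      if (m == 0) next
      xs <- sort(runif(2 * m, -600, 600))
      for (j in seq_len(m)) {
        r <- rect_polygon(locs[i, 1] + xs[2 * j - 1], -300,
                          locs[i, 1] + xs[2 * j], 300)
        polys[[length(polys) + 1]] <- r
        want <- want + poly_area(r) / sb * durs[i] / 24
      }
    }
    if (length(polys) == 0) next
    lay <- greenspace_layer(vegetation = polys)
    expect_equal(vegetation_coverage(sp, lay), want, tolerance = 1e-9)
  }
})

test_that("coverage is monotone in the polygon set and invariant to time swaps", {
  d <- make_diary(c(10, 14), locs = rbind(c(0, 0), c(40000, 0)))
  sp <- delineate(d)
  p1 <- rect_polygon(-500, -500, 0, 0)
  p2 <- rect_polygon(39800, -300, 40200, 300)
  c1 <- vegetation_coverage(sp, greenspace_layer(vegetation = list(p1)))
  c2 <- vegetation_coverage(sp, greenspace_layer(vegetation = list(p1, p2)))
  expect_gte(c2, c1)

  # same per-buffer fractions at both stays -> shifting hours changes nothing
  q1 <- rect_polygon(-300, -300, 300, 300)
  q2 <- rect_polygon(39700, -300, 40300, 300)
  lay <- greenspace_layer(vegetation = list(q1, q2))
  d2 <- make_diary(c(4, 20), locs = rbind(c(0, 0), c(40000, 0)))
  expect_equal(vegetation_coverage(sp, lay),
               vegetation_coverage(delineate(d2), lay), tolerance = 1e-9)
})

test_that("accessibility averages stay-to-nearest-greenspace distances", {
  gs <- list(rect_polygon(100, -50, 200, 50),    # 100 m east of stay 1
             rect_polygon(39600, -50, 39700, 50)) # 300 m west of stay 2
  lay <- greenspace_layer(greenspaces = gs)
  d <- make_diary(c(12, 12), locs = rbind(c(0, 0), c(40000, 0)))
  expect_equal(accessibility(d, lay), 200)

  inside <- make_diary(24, locs = cbind(150, 0))
  expect_equal(accessibility(inside, lay), 0)
  single <- make_diary(24, locs = cbind(0, 0))
  expect_equal(accessibility(single, lay), 100)

  expect_error(accessibility(d, greenspace_layer(vegetation = gs)), "empty")
  # restricted search: stay 2 has nothing within its buffer
  far <- greenspace_layer(greenspaces = gs[1])
  expect_warning(a <- accessibility(d, far, within_buffer_only = TRUE), "buffer")
  expect_equal(a, 100)
})

test_that("exposure_profile bundles the three indicators per participant", {
  d <- make_diary(c(12, 9), classes = c("residence", "work"), travel_hours = 3,
                  id = "P1")
  lay <- saturating_layer()
  pr <- exposure_profile(d, layer = lay)
  expect_equal(pr$participant_id, "P1")
  expect_equal(pr$GE1, 1, tolerance = 1e-9)
  expect_equal(pr$GE2, 1, tolerance = 1e-9)
  expect_equal(pr$GE3, 0)
})
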