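test_that("PM fraction weights implement the boundary-inclusive sharp cut", {
  cfg <- samplerConfig()
  expect_equal(pmWeight(2.5, cfg, "pm25"), 1)
  expect_equal(pmWeight(3, cfg, "pm25"), 0)
  expect_equal(pmWeight(3, cfg, "pm10"), 1)
  expect_equal(pmWeight(10, cfg, "pm10"), 1)
  expect_equal(pmWeight(10.001, cfg, "pm10"), 0)
  # non-increasing in diameter for both conventions
  d <- sort(runif(50, 0.1, 15))
  for (cv in c("sharp", "smooth")) {
    cc <- samplerConfig(pmConvention = cv)
    expect_true(all(diff(pmWeight(d, cc, "pm25")) <= 0))
  }
  expect_error(pmWeight(1, cfg, "pm1"), "unknown fraction")
})

test_that("single-particle concentration matches a hand-evaluated formula", {
  cfg <- samplerConfig(efficiencyCurve = unitEfficiencyCurve())
  p <- data.frame(stub_id = "s", particle = 1L, d_ae_um = 1.7486,
                  mass_ng = 3.2e-3)
  occ <- list(occasion_id = "o", duration_h = 24, surface = "CT")
  res <- suppressWarnings(stubConcentration(p, 1, occ, cfg))
  # independent hand evaluation: v = settling + Stokes-Einstein diffusion
  d_m <- 1.7486e-6
  cc <- 1 + (2 * 0.0665 / 1.7486) *
    (1.142 + 0.558 * exp(-0.999 * 1.7486 / (2 * 0.0665)))
  vs <- 1000 * 9.80665 * d_m^2 * cc / (18 * 1.81e-5)
  vd <- 1.380649e-23 * 293 * cc / (3 * pi * 1.81e-5 * d_m) / 1e-3
  want <- 3.2e-3 * 1e-6 / (vs + vd) / (1e-6 * 24 * 3600)
  expect_equal(res$pm25, want, tolerance = 1e-10)
  expect_equal(res$pm10, want, tolerance = 1e-10)
})

test_that("concentration is linear in duration, area, and mass", {
  cfg <- samplerConfig(efficiencyCurve = unitEfficiencyCurve())
  p <- data.frame(stub_id = "s", particle = 1:3, d_ae_um = c(1, 2, 6),
                  mass_ng = c(1e-3, 8e-3, 0.2))
  occ <- function(h) list(occasion_id = "o", duration_h = h)
  c24 <- suppressWarnings(stubConcentration(p, 2, occ(24), cfg))
  c12 <- suppressWarnings(stubConcentration(p, 2, occ(12), cfg))
  expect_equal(c12$pm10, 2 * c24$pm10)
  cA <- suppressWarnings(stubConcentration(p, 4, occ(24), cfg))
  expect_equal(cA$pm10, c24$pm10 / 2)
  p2 <- p; p2$mass_ng <- 2 * p2$mass_ng
  cM <- suppressWarnings(stubConcentration(p2, 2, occ(24), cfg))
  expect_equal(cM$pm10, 2 * c24$pm10)
  expect_equal(cM$pm25, 2 * c24$pm25)
})

test_that("empty particle lists give zero concentrations", {
  cfg <- samplerConfig()
  res <- suppressWarnings(stubConcentration(
    data.frame(), 1, list(occasion_id = "o", duration_h = 8), cfg))
  expect_equal(res$pm25, 0)
  expect_equal(res$pm10, 0)
  expect_identical(res$pm25_count, 0L)
})

test_that("zero efficiency or deposition velocity is a named error", {
  cfg <- samplerConfig(efficiencyCurve = efficiencyCurve(c(1, 10), c(0, 0)))
  p <- data.frame(stub_id = "s", particle = 7L, d_ae_um = 2, mass_ng = 1e-3)
  expect_error(
    stubConcentration(p, 1, list(occasion_id = "o", duration_h = 8), cfg),
    "collection efficiency")
})

test_that("low fraction counts trigger the adequacy warning", {
  cfg <- samplerConfig(efficiencyCurve = unitEfficiencyCurve())
  p <- data.frame(stub_id = "s", particle = 1:3, d_ae_um = c(1, 2, 3),
                  mass_ng = rep(1e-3, 3))
  w <- capture_warnings(
    stubConcentration(p, 1, list(occasion_id = "o", duration_h = 8), cfg))
  expect_true(any(grepl("counting statistics", w)))
})

test_that("blank correction subtracts the per-surface field-blank mean", {
  res <- data.frame(
    occasion_id = c("a", "b", "fb1", "fb2", "tb"),
    surface = "PC",
    role = c("sample", "sample", "field_blank", "field_blank",
             "transport_blank"),
    pm25 = c(0.010, 0.030, 0.010, 0.014, 0.002),
    pm10 = c(0.050, 0.080, 0.020, 0.024, 0.003),
    duration_h = 24, blank_corrected = FALSE)
  out <- blankCorrect(res)
  expect_equal(out$blankStats$mean[out$blankStats$fraction == "pm25"], 0.012)
  # sample 0.010 - blank mean 0.012 -> -0.002, retained
  expect_equal(out$results$pm25[1], -0.002)
  # corrected field blanks average zero
  fb <- out$results[out$results$role == "field_blank", ]
  expect_lt(abs(mean(fb$pm25)), 1e-15)
  expect_lt(abs(mean(fb$pm10)), 1e-15)
  # transport blanks untouched
  expect_equal(out$results$pm25[5], 0.002)
  expect_false(out$results$blank_corrected[5])
  expect_true(all(out$results$blank_corrected[1:4]))
})

test_that("all-zero blanks leave results unchanged", {
  res <- data.frame(occasion_id = c("a", "fb"), surface = "CT",
                    role = c("sample", "field_blank"),
                    pm25 = c(0.02, 0), pm10 = c(0.05, 0),
                    duration_h = 24, blank_corrected = FALSE)
  out <- blankCorrect(res)
  expect_equal(out$results$pm25[1], 0.02)
  expect_equal(out$results$pm10[1], 0.05)
})

test_that("a surface without field blanks errors unless disabled", {
  res <- data.frame(occasion_id = "a", surface = "CT", role = "sample",
                    pm25 = 0.02, pm10 = 0.05, duration_h = 24,
                    blank_corrected = FALSE)
  expect_error(blankCorrect(res), "no field blank")
  expect_warning(out <- blankCorrect(res, requireBlanks = FALSE),
                 "uncorrected")
  expect_equal(out$results$pm25, 0.02)
  expect_false(out$results$blank_corrected)
})

test_that("duration weighting averages 1 and 3 over 8 and 16 h to 7/3", {
  r <- data.frame(pm25 = c(1, 3), pm10 = c(1, 3), duration_h = c(8, 16))
  m <- timeWeightedMean(r)
  expect_equal(unname(m["pm25"]), 7 / 3)
  expect_equal(unname(m["pm10"]), 7 / 3)
  # identity on a single occasion
  one <- timeWeightedMean(r[1, ])
  expect_equal(unname(one["pm25"]), 1)
  # splitting an occasion into equal-value halves changes nothing
  split <- data.frame(pm25 = c(1, 3, 3), pm10 = c(1, 3, 3),
                      duration_h = c(8, 6, 10))
  expect_equal(timeWeightedMean(split), m)
  expect_error(timeWeightedMean(r[0, ]), "no results")
})

test_that("sampler-to-reference ratio is a plain percentage", {
  expect_equal(samplerVsReferenceRatio(0.05, 0.05), 100)
  expect_equal(samplerVsReferenceRatio(0.025, 0.05), 50)
  expect_error(samplerVsReferenceRatio(1, 0), "positive")
  expect_error(samplerVsReferenceRatio(1, -2), "positive")
})

test_that("PM2.5 never exceeds PM10 for uncorrected sharp-cut results", {
  cfg <- samplerConfig()
  set.seed(88)
  for (i in 1:25) {
    sc <- truthScenario(runif(1, 0.05, 3), cmd = runif(1, 1, 6),
                        gsd = runif(1, 1.2, 2.5),
                        durationHours = runif(1, 4, 25),
                        depositionArea = 0.5, nTiles = 4L,
                        contaminationRate = 0, seed = 1000L + i)
    tr <- samplePopulation(sc, cfg)
    res <- suppressWarnings(stubConcentration(
      tr, 0.5, list(occasion_id = "x", duration_h = sc@durationHours), cfg))
    expect_lte(res$pm25, res$pm10)
  }
})

test_that("occasion tables compute durations from timestamps", {
  st <- as.POSIXct("2016-05-10 08:00", tz = "UTC")
  occ <- samplingOccasions(c("a", "b"), surface = c("PC", "CT"),
                           start = c(st, st), end = c(st + 8 * 3600,
                                                      st + 16 * 3600))
  expect_equal(occ$duration_h, c(8, 16))
  expect_error(samplingOccasions("a", "PC", start = st, end = st),
               "after start")
})
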