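test_that("noise-free runs give one trace per detectable isotopologue", {
  cmp <- trueCompounds("C19H18O7", 5, 1e7, intensity_cv = 0)
  cfg <- experimentConfig(run_duration = 10, intensity_cv = 0,
                          rt_jitter_sd = 0, mz_jitter_ppm = 0,
                          noise_peak_rate = 0, seed = 1)
  sim <- simulateExperiment(cmp, cfg)
  tr <- buildMassTraces(sim$runs[[1]])
  expect_identical(length(tr), 3L)  # A, A+1, A+2
  mzs <- sort(sapply(tr, `[[`, "mz"))
  theo <- mzFromNeutral(isotopePattern("C19H18O7", 3)$mass)
  expect_equal(mzs, theo, tolerance = 2e-6)
})

test_that("ions 10 ppm apart stay in separate traces at 5 ppm tolerance", {
  mz1 <- 400
  mz2 <- 400 * (1 + 10e-6)
  rt <- seq(1, 1.2, by = 1 / 120)
  peaks <- lapply(seq_along(rt), function(i)
    cbind(mz = c(mz1, mz2), intensity = c(2e5, 3e5)))
  run <- MsRun(rt, peaks, runId = "sample_1")
  tr <- buildMassTraces(run, tol_ppm = 5)
  expect_identical(length(tr), 2L)
  expect_equal(sort(sapply(tr, `[[`, "mz")), c(mz1, mz2), tolerance = 1e-9)
})

test_that("degenerate runs are handled", {
  empty <- MsRun(numeric(0), list(), runId = "sample_1")
  expect_identical(buildMassTraces(empty), list())
  run <- MsRun(c(1, 2), list(cbind(400, 1e5), cbind(400, 1e5)))
  run@scanTime <- c(2, 1)  # bypass constructor checks
  expect_error(buildMassTraces(run), "ordered")
})

test_that("every centroid is used at most once by the traces", {
  sc <- smallScenario(seed = 21)
  sim <- simulateExperiment(sc$compounds, sc$config)
  run <- sim$runs[[1]]
  tr <- buildMassTraces(run)
  traced <- sum(unlist(lapply(tr, `[[`, "intensity")))
  total <- sum(unlist(lapply(peaksData(run), function(p) p[, 2])))
  expect_lte(traced, total + 1e-6)
})

test_that("peak detection applies the S/N and height thresholds", {
  clean <- makeGaussianTrace(amplitude = 1e6, noise_sd = 1e3,
                             from = 3, to = 7, seed = 31)
  f <- detectPeaks(clean)
  expect_identical(nrow(f), 1L)
  expect_gt(f$snr, 100)
  expect_equal(f$rt_apex, 5, tolerance = 0.02)
  expect_true(f$rt_start < f$rt_apex && f$rt_apex < f$rt_end)

  low <- makeGaussianTrace(amplitude = 5e4)
  expect_identical(nrow(detectPeaks(low)), 0L)

  flat <- list(mz = 400, rt = seq(0, 1, by = 1 / 120),
               intensity = rep(0, 121), scan = 1:121)
  expect_identical(nrow(detectPeaks(flat)), 0L)
})

test_that("two overlapping elution peaks are split at the valley", {
  t1 <- makeGaussianTrace(apex_rt = 5, amplitude = 8e5, from = 4.5, to = 6)
  t2 <- makeGaussianTrace(apex_rt = 5.5, amplitude = 6e5, from = 4.5, to = 6)
  tr <- list(mz = 400, rt = t1$rt, intensity = t1$intensity + t2$intensity,
             scan = t1$scan)
  f <- detectPeaks(tr)
  expect_identical(nrow(f), 2L)
  expect_equal(f$rt_apex, c(5, 5.5), tolerance = 0.03)
})

test_that("lowering thresholds never removes a detected feature", {
  tr <- makeGaussianTrace(amplitude = 3e5, noise_sd = 2e4, baseline = 5e4,
                          from = 3, to = 7, seed = 41)
  strict <- detectPeaks(tr, snr_min = 3, min_height = 1e5)
  loose <- detectPeaks(tr, snr_min = 1, min_height = 1e4)
  key <- function(f) paste(f$rt_apex, f$height)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("trapezoidal areas match closed forms", {
  # rectangle: constant h over w seconds
  rect <- list(rt = seq(0, 1, by = 1 / 600), intensity = rep(1000, 601))
  expect_equal(integrateArea(rect, 0, 1), 1000 * 60, tolerance = 0.01)
  # Gaussian: A * sigma_s * sqrt(2*pi)
  g <- makeGaussianTrace(apex_rt = 5, sigma = 0.05, amplitude = 1e6,
                         from = 4.5, to = 5.5, dt_s = 0.2)
  expect_equal(integrateArea(g, 4.5, 5.5), 1e6 * 0.05 * 60 * sqrt(2 * pi),
               tolerance = 0.02)
  expect_error(integrateArea(g, 4.999, 5.001), "fewer than two")
})

test_that("noise-free simulated features recover the planted ground truth", {
  cmp <- trueCompounds(c("C19H18O7", "C20H20O8", "C27H32O14"),
                       c(4, 7, 10), c(2e7, 1e7, 8e6), intensity_cv = 0)
  cfg <- experimentConfig(run_duration = 14, intensity_cv = 0,
                          rt_jitter_sd = 0, mz_jitter_ppm = 0,
                          noise_peak_rate = 0, seed = 1)
  sim <- simulateExperiment(cmp, cfg)
  f <- detectFeatures(sim$runs[[1]])
  mono <- mzFromNeutral(monoisotopicMass(cmp$formula))
  for (i in seq_len(nrow(cmp))) {
    hit <- which(abs(ppmError(f$mz, mono[i])) <= 5)
    expect_identical(length(hit), 1L)
    expect_lte(abs(f$rt_apex[hit] - cmp$retention_time[i]),
               cfg$scan_interval / 60 + 1e-9)
  }
})
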