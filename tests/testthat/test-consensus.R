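test_that("a uniform RT shift is corrected and all compounds matched", {
  cmp <- trueCompounds(c("C19H18O7", "C15H12O5", "C27H32O14", "C20H20O8"),
                       c(3, 5, 7, 9), c(2e7, 1e7, 8e6, 5e6),
                       intensity_cv = 0)
  cfg <- experimentConfig(run_duration = 12, intensity_cv = 0,
                          rt_jitter_sd = 0, mz_jitter_ppm = 0,
                          noise_peak_rate = 0, seed = 1)
  sim <- simulateExperiment(cmp, cfg)
  tabs <- lapply(sim$runs, detectFeatures)
  # impose a known uniform shift on one run
  tabs[["control_2"]]$rt_apex <- tabs[["control_2"]]$rt_apex + 0.05
  cs <- collapseIsotopologues(alignRuns(tabs))
  expect_identical(nrow(cs), nrow(cmp))
  expect_equal(unname(S4Vectors::metadata(cs)$rt_offsets[["control_2"]]),
               0.05, tolerance = 1e-6)
  expect_true(all(!is.na(areaMatrix(cs))))
})

test_that("same-mass features beyond the RT tolerance stay separate", {
  f <- data.frame(run_id = "x", mz = 400.007276, neutral_mass = 399.0,
                  rt_apex = c(10.0, 10.2), rt_start = c(9.9, 10.1),
                  rt_end = c(10.1, 10.3), height = c(5e5, 5e5),
                  area = c(1e6, 1e6), snr = 100)
  tabs <- list(sample_1 = f, control_1 = f)
  cs <- alignRuns(tabs)
  expect_identical(nrow(cs), 2L)
})

test_that("alignment requires at least two runs", {
  f <- data.frame(run_id = "sample_1", mz = 400, neutral_mass = 399,
                  rt_apex = 5, rt_start = 4.9, rt_end = 5.1,
                  height = 1e6, area = 1e6, snr = 10)
  expect_error(alignRuns(list(sample_1 = f)), "two runs")
})

test_that("no feature is used twice and all matched features are kept", {
  sc <- smallScenario(seed = 13)
  sim <- simulateExperiment(sc$compounds, sc$config)
  tabs <- lapply(sim$runs, detectFeatures)
  cs <- alignRuns(tabs)
  members <- unlist(strsplit(SummarizedExperiment::rowData(cs)$member_features,
                             ";"))
  expect_identical(anyDuplicated(members), 0L)
  expect_identical(length(members), sum(sapply(tabs, nrow)))
})

test_that("isotopologue satellites collapse onto the monoisotopic record", {
  cmp <- trueCompounds("C27H32O14", 5, 5e7, intensity_cv = 0)
  cfg <- experimentConfig(run_duration = 10, intensity_cv = 0,
                          rt_jitter_sd = 0, mz_jitter_ppm = 0,
                          noise_peak_rate = 0, seed = 1)
  sim <- simulateExperiment(cmp, cfg)
  tabs <- lapply(sim$runs, detectFeatures)
  cs <- alignRuns(tabs)
  expect_gt(nrow(cs), 1L)  # A+1 (and A+2) detected separately
  collapsed <- collapseIsotopologues(cs)
  expect_identical(nrow(collapsed), 1L)
  expect_equal(consensusMass(collapsed), monoisotopicMass("C27H32O14"),
               tolerance = 5e-6)
  # idempotent
  expect_identical(nrow(collapseIsotopologues(collapsed)), 1L)
})

test_that("a 1 Da mass pair with distinct RT is not merged", {
  s <- matrix(c(1e6, 1e6), 2, 4); ctl <- s
  cs <- makeConsensusSet(s, ctl, mass = c(400, 401.00336), rt = c(5, 5.5))
  expect_identical(nrow(collapseIsotopologues(cs)), 2L)
})

test_that("a larger 'satellite' is kept with a warning", {
  s <- matrix(c(1e5, 1e6), 2, 4); ctl <- s
  cs <- makeConsensusSet(s, ctl, mass = c(400, 401.00336), rt = c(5, 5.0))
  expect_warning(out <- collapseIsotopologues(cs), "larger area")
  expect_identical(nrow(out), 2L)
})

test_that("default-noise recovery yields one complete consensus per compound", {
  lib <- defaultPhantomLibrary()
  set.seed(17)
  cmp <- lib[sort(sample(nrow(lib), 25)), ]
  cfg <- experimentConfig(seed = 17)
  sim <- simulateExperiment(cmp, cfg)
  tabs <- lapply(sim$runs, detectFeatures)
  cs <- collapseIsotopologues(alignRuns(tabs))
  mono <- monoisotopicMass(cmp$formula)
  ok <- vapply(seq_len(nrow(cmp)), function(i) {
    j <- which(abs(ppmError(consensusMass(cs), mono[i])) <= 5 &
                 abs(consensusRT(cs) - cmp$retention_time[i]) <= 0.15)
    length(j) == 1 && all(!is.na(areaMatrix(cs)[j, ]))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
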