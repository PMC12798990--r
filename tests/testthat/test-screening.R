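test_that("per-pair PAR, mean and SD follow their definitions", {
  eq <- computePAR(c(1e6, 2e6, 3e6, 4e6), c(1e6, 2e6, 3e6, 4e6), 1e6)
  expect_equal(eq$par_values, rep(1, 4))
  expect_equal(eq$par_mean, 1)
  expect_equal(eq$par_sd, 0)

  dbl <- computePAR(2 * c(1e6, 2e6, 3e6, 4e6), c(1e6, 2e6, 3e6, 4e6), 1e6)
  expect_equal(dbl$par_mean, 2)
  expect_equal(dbl$par_sd, 0)

  # pairs (2.0, 1.9, 2.1, 2.0) vs 1: hand-computed mean/SD
  h <- computePAR(c(2.0, 1.9, 2.1, 2.0) * 1e6, rep(1e6, 4), 1e6)
  expect_equal(h$par_mean, 2.00)
  expect_equal(h$par_sd, sd(c(2.0, 1.9, 2.1, 2.0)), tolerance = 1e-12)
  expect_equal(h$par_sd, 0.0816497, tolerance = 1e-5)
})

test_that("missing control areas are imputed at the floor and flagged", {
  pr <- computePAR(c(1e7, 1e7, 1e7, 1e7), c(1e6, NA, 1e6, 1e6),
                   floor_area = 5e5)
  expect_true(pr$imputed_control)
  expect_equal(pr$par_values[2], 1e7 / 5e5)
  # a missing sample drops the pair instead
  pr2 <- computePAR(c(1e7, NA, 1e7, 1e7), c(1e6, 1e6, 1e6, 1e6), 5e5)
  expect_identical(pr2$n_pairs, 3L)
  # fewer than two usable pairs: excluded
  pr3 <- computePAR(c(1e7, NA, NA, NA), c(1e6, 1e6, 1e6, 1e6), 5e5)
  expect_true(is.na(pr3$par_mean))
})

test_that("the t-test matches its closed form and handles degeneracy", {
  expect_equal(tTestAreas(c(5, 5, 5, 5), c(5, 5, 5, 5)), 1)
  expect_warning(p0 <- tTestAreas(c(5, 5, 5), c(6, 6, 6)), "zero variance")
  expect_equal(p0, 0)
  expect_error(tTestAreas(5, c(1, 2)), "at least two")

  x <- c(10, 12, 11, 13); y <- c(5, 6, 5, 6)
  p <- tTestAreas(x, y)
  expect_equal(p, pooledTP(x, y), tolerance = 1e-10)
  # the exact permutation test agrees on the decision at alpha = 0.05
  expect_lt(p, 0.05)
  expect_lt(exactPermP(x, y), 0.05)

  set.seed(55)
  for (i in 1:20) {
    a <- rnorm(4, 10, 2); b <- rnorm(4, 10 + runif(1, 0, 4), 2)
    expect_equal(tTestAreas(a, b), pooledTP(a, b), tolerance = 1e-10)
  }
  # Welch variant differs under unequal variances
  a <- c(10, 11, 12, 13); b <- c(1, 9, 15, 30)
  expect_false(isTRUE(all.equal(tTestAreas(a, b, "welch"),
                                tTestAreas(a, b, "student"))))
})

test_that("the selection rule is strict on both thresholds", {
  rep <- data.frame(compound_id = c("a", "b", "c", "d", "e"),
                    par_mean = c(1.99, 0.90, 1.50, 1.0, 1.2),
                    p_value = c(0.001, 0.0001, 0.20, 0.001, 0.05))
  sel <- selectLigands(rep)
  expect_identical(sel$compound_id, "a")   # b: PAR <= 1; c: p >= alpha
  # d sits exactly on PAR = 1, e exactly on p = 0.05: both excluded
  expect_false(any(c("d", "e") %in% sel$compound_id))
  # sorted by decreasing mean PAR
  rep2 <- data.frame(compound_id = c("x", "y"), par_mean = c(1.2, 1.8),
                     p_value = c(0.01, 0.01))
  expect_identical(selectLigands(rep2)$compound_id, c("y", "x"))
  expect_error(selectLigands(rep[0, ]), "empty")
})

test_that("raising a compound's mean PAR never deselects it", {
  set.seed(66)
  for (i in 1:50) {
    pm <- runif(1, 0.5, 3); p <- runif(1, 0, 0.2)
    base <- data.frame(compound_id = "z", par_mean = pm, p_value = p)
    up <- base; up$par_mean <- pm + runif(1, 0, 2)
    if (nrow(selectLigands(base)) == 1)
      expect_identical(nrow(selectLigands(up)), 1L)
  }
})

test_that("screenCompounds reproduces known statistics on a constructed set", {
  s <- rbind(c(2.0, 1.9, 2.1, 2.0) * 1e6,
             c(1e6, 1.1e6, 0.9e6, 1e6),
             c(1e7, 1e7, 1e7, 1e7))
  ctl <- rbind(rep(1e6, 4),
               c(1e6, 1.1e6, 0.9e6, 1e6),
               c(NA, NA, NA, NA))
  cs <- makeConsensusSet(s, ctl, median_peak_width_s = 12)
  # compound 3: constant sample vs fully-imputed constant control areas is
  # the documented zero-variance degenerate case (p = 0 with a warning)
  expect_warning(out <- screenCompounds(cs), "zero variance")
  rd <- SummarizedExperiment::rowData(out)
  expect_equal(rd$par_mean[1], 2.0)
  expect_equal(rd$par_mean[2], 1.0)
  expect_true(rd$selected[1])
  expect_false(rd$selected[2])
  # compound 3 absent from every control: imputed at 1e5 * 12 s
  expect_true(rd$imputed_control[3])
  expect_equal(rd$par_mean[3], 1e7 / (1e5 * 12))
  expect_true(rd$selected[3])
  rep <- screeningReport(out)
  expect_identical(nrow(rep), 3L)
  expect_true(all(c("par_1", "par_4", "p_value", "selected") %in% names(rep)))
})

test_that("null compounds are selected at well below the nominal rate", {
  # enrichment 1 everywhere: the PAR > 1 conjunct makes the rule one-sided,
  # so the false-selection rate must stay below alpha
  cmp <- trueCompounds(rep("C19H18O7", 200),
                       retention_time = seq(1, 20, length.out = 200),
                       base_area = 1e7, enrichment = 1, intensity_cv = 0.1)
  hits <- 0; total <- 0
  for (s in 1:10) {
    ar <- simulateAreas(cmp, experimentConfig(seed = s))
    for (i in 1:200) {
      pv <- ar$sample[i, ] / ar$control[i, ]
      p <- tTestAreas(ar$sample[i, ], ar$control[i, ])
      hits <- hits + (mean(pv) > 1 && p < 0.05)
      total <- total + 1
    }
  }
  se <- sqrt(0.05 * 0.95 / total)
  expect_lte(hits / total, 0.05 + 3 * se)
})

test_that("inhibition percentages follow the absorbance formula", {
  expect_equal(inhibitionPercent(1, 1), 0)
  expect_equal(inhibitionPercent(1, 0), 100)
  expect_equal(inhibitionPercent(1.0000, 0.7566), 24.34)
  expect_equal(inhibitionPercent(c(2, 4), c(1, 1)), c(50, 75))
  expect_error(inhibitionPercent(0, 1), "positive")
  expect_error(inhibitionPercent(1, -0.1), "non-negative")
})
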