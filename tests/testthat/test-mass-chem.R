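test_that("monoisotopic masses match reference values", {
  # polymethoxyflavone C19H18O7, neutral mass printed as 358.1052
  expect_lt(abs(ppmError(358.1052, monoisotopicMass("C19H18O7"))), 5)
  # flavanone glycoside, hand summation of atomic masses: 610.1898
  expect_equal(monoisotopicMass("C28H34O15"), 610.1898, tolerance = 0.0005 / 610)
  expect_identical(monoisotopicMass(c(C = 0, H = 0, O = 0)), 0)
  expect_equal(monoisotopicMass("H2O"), 18.0105647, tolerance = 1e-6)
})

test_that("mass is additive in composition", {
  set.seed(101)
  for (i in 1:25) {
    f1 <- c(C = sample(0:40, 1), H = sample(0:80, 1), O = sample(0:20, 1))
    f2 <- c(C = sample(0:40, 1), H = sample(0:80, 1), O = sample(0:20, 1))
    expect_equal(monoisotopicMass(f1 + f2),
                 monoisotopicMass(f1) + monoisotopicMass(f2),
                 tolerance = 1e-9)
  }
})

test_that("formula parsing validates input", {
  expect_identical(unname(parseFormula("C19H18O7")[1, ]), c(19L, 18L, 7L))
  expect_identical(unname(parseFormula("CH4")[1, ]), c(1L, 4L, 0L))
  expect_error(parseFormula("C6H12N2"), "unsupported element")
  expect_error(monoisotopicMass(c(C = -1, H = 0, O = 0)), "negative")
  expect_identical(formulaString(parseFormula("C19H18O7")), "C19H18O7")
})

test_that("adduct conversion round-trips exactly and rejects bad input", {
  expect_equal(mzFromNeutral(358.1052), 359.1125, tolerance = 0.0005 / 359)
  expect_error(mzFromNeutral(0), "positive")
  expect_error(mzFromNeutral(100, adduct = "[M+Na]+"), "supported")
  set.seed(7)
  m <- runif(50, 100, 900)
  expect_equal(neutralFromMz(mzFromNeutral(m)), m, tolerance = 1e-12)
})

test_that("RDBE follows C - H/2 + 1", {
  expect_equal(unname(rdbe("C19H18O7")), 11)
  expect_equal(unname(rdbe("CH4")), 0)
  expect_equal(unname(rdbe(c(C = 0, H = 2, O = 1))), 0)  # water
  expect_equal(unname(rdbe("C2H5O")), 0.5)               # half-integer allowed
})

test_that("formula enumeration matches the exhaustive-search oracle", {
  hits <- enumerateFormulas(358.1052)
  expect_true("C19H18O7" %in% hits$formula)
  expect_identical(enumerateFormulas(16.0313)$formula, "CH4")
  expect_error(enumerateFormulas(300, tol_ppm = 0), "positive")

  set.seed(202)
  masses <- c(610.1894, runif(10, 150, 650))
  for (qm in masses) {
    got <- enumerateFormulas(qm)
    want <- oracleEnumerate(qm)
    expect_identical(nrow(got), nrow(want))
    key <- function(d) sort(paste(d$n_C, d$n_H, d$n_O))
    expect_identical(key(got), key(want))
  }
})

test_that("enumeration output is sorted by |ppm| with lexicographic ties", {
  got <- enumerateFormulas(500, tol_ppm = 20)
  expect_false(is.unsorted(abs(got$ppm_error)))
  expect_true(all(abs(got$ppm_error) <= 20))
  expect_true(all(got$rdbe >= 0 & got$rdbe <= 40))
})

test_that("isotope patterns follow binomial 13C/18O statistics", {
  p <- isotopePattern("C19H18O7", 2)
  expect_equal(p$abundance[2], 19 * 0.0107, tolerance = 0.05)
  p1 <- isotopePattern(c(C = 1, H = 0, O = 0), 2)
  expect_equal(p1$abundance[2], 0.0107, tolerance = 0.02)
  p3 <- isotopePattern("C28H34O15", 4)
  expect_true(all(p3$abundance >= 0))
  expect_equal(p3$mass, p3$mass[1] + p3$k * 1.00336, tolerance = 1e-9)
  expect_equal(p3$abundance[1], 1)
  expect_error(isotopePattern(c(C = 0, H = 0, O = 0)), "empty")
})

test_that("packaged ligand formulas are mass-consistent with printed MWs", {
  kb <- loadKnowledgeBase()
  ref <- kb$ligands[1:20, ]  # the reference-standard block
  expect_identical(unique(ref$source), "reference_standard")
  expect_true(all(abs(ppmError(ref$detected_mw, ref$theoretical_mass)) <= 5))
  # all rows except the flagged placeholders/outlier pass the same audit
  audit <- kb$ligands[!kb$ligands$flag %in% c("mw_placeholder", "mw_outlier"), ]
  expect_true(all(abs(ppmError(audit$detected_mw, audit$theoretical_mass)) <= 5))
})
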