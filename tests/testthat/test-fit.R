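test_that("chi-square tail machinery behaves at the edges", {
  expect_equal(chiSqTail(0, 5), 1)
  expect_equal(chiSqTail(1e6, 1), 0)
  expect_error(chiSqTail(-1, 2), "negative")
  expect_error(chiSqTail(3, 0), "df")
})

test_that("AIC and the likelihood-ratio test follow their definitions", {
  mkFit <- function(m2ll, k) {
    m <- ntfModel("ABDSTE")
    new("NTFFit", model = m, equilibrium = solveEquilibrium(m),
        minus2LL = m2ll, k = as.integer(k), converged = TRUE,
        nEvaluations = 1L, bestStart = 1L,
        startDiagnostics = data.frame())
  }
  expect_equal(aic(mkFit(8200, 20)), 8240)
  full <- mkFit(1000, 10); red <- mkFit(1007.8, 4)
  t1 <- lrTest(full, red)
  expect_equal(t1@chi2, 7.8, tolerance = 1e-12)
  expect_equal(t1@df, 6L)
  expect_equal(t1@p, pchisq(7.8, 6, lower.tail = FALSE))
  expect_false(t1@retained)            # p = .25 > .10: reduction accepted
  # AIC difference of a nested pair is chi2 - 2 df
  expect_equal(aic(mkFit(1007.8, 4)) - aic(full), 7.8 - 2 * 6)
  # tiny negative statistics clamp to zero with a flag
  t2 <- lrTest(mkFit(1000, 10), mkFit(1000 - 1e-8, 4))
  expect_equal(t2@chi2, 0)
  expect_true(t2@clamped)
  expect_equal(t2@p, 1)
  # larger negatives signal an unconverged full model
  expect_error(lrTest(mkFit(1000, 10), mkFit(990, 4)), "unconverged")
  expect_error(lrTest(mkFit(1000, 4), mkFit(1000, 10)), "not nested")
})

test_that("fitting recovers the optimum stably on one data set", {
  truth <- ntfTruthPreset("studylike_sexeq")
  fam <- simulateSmall(truth, nFam = 150L, seedPop = 21L, seedFam = 22L)
  fit <- fitNTF(truth, fam, nStarts = 1L, control = quickControl())
  expect_true(fit@converged)
  expect_equal(aic(fit), minus2LL(fit) + 2 * nFreeParams(fit))
  # refitting from the optimum does not move the likelihood
  refit <- fitNTF(estimates(fit), fam, nStarts = 1L,
                  control = quickControl())
  expect_equal(minus2LL(refit), minus2LL(fit), tolerance = 1e-6)
  # a nested submodel can never fit better
  red <- fitNTF(reduceModel(estimates(fit), drop = "d"), fam,
                nStarts = 1L, control = quickControl())
  expect_gte(minus2LL(red), minus2LL(fit) - 1e-6)
  tst <- lrTest(fit, red)
  expect_equal(tst@df, 3L)
  # report writers emit readable key-value text
  p1 <- tempfile(); p2 <- tempfile()
  writeReport(fit, p1); writeReport(tst, p2)
  expect_true(any(grepl("^minus2LL:", readLines(p1))))
  expect_true(any(grepl("^chi2:", readLines(p2))))
})

test_that("the q off-diagonal constraint binds the fitted equilibrium", {
  truth <- ntfTruthPreset("studylike_sexeq")
  fam <- simulateSmall(truth, nFam = 150L, seedPop = 25L, seedFam = 26L)
  full <- fitNTF(truth, fam, nStarts = 1L, control = quickControl())
  expect_gt(abs(qMatrix(equilibrium(full))[1, 2]), 0.01)
  con <- fitNTF(reduceModel(estimates(full), constrainQ = TRUE), fam,
                nStarts = 1L, control = quickControl())
  expect_lt(abs(qMatrix(equilibrium(con))[1, 2]), 1e-3)
  expect_gte(minus2LL(con), minus2LL(full) - 1e-4)
  expect_equal(nFreeParams(full) - nFreeParams(con), 1L)
})
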