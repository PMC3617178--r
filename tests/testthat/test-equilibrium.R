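test_that("random mating gives the identity equilibrium exactly", {
  m <- reduceModel(fullFeatureTruth(), drop = "mu")
  eq <- solveEquilibrium(m)
  expect_identical(qMatrix(eq), diag(2))
  expect_identical(qBMatrix(eq), diag(2))
  expect_true(all(gammaMatrix(eq) == 0))
  expect_true(all(eq@wM == 0) && all(eq@wF == 0))
  # homogamy is random mating with respect to phenotype
  eqh <- solveEquilibrium(homogamyTruth())
  expect_identical(qMatrix(eqh), diag(2))
})

test_that("univariate fixed point matches the closed-form quadratic root", {
  # q is the smaller root of a^2 mu q^2 - q + 1 = 0
  for (ps in list(c(0.5, 0.2), c(0.3, 0.1), c(0.8, 0.25), c(0.6, -0.15))) {
    a2 <- ps[1]; mu <- ps[2]
    expect_true(4 * a2 * mu < 1)
    eq <- solveEquilibrium(univariateTruth(a2, mu), tol = 1e-12)
    closed <- (1 - sqrt(1 - 4 * a2 * mu)) / (2 * a2 * mu)
    expect_equal(qMatrix(eq)[1, 1], closed, tolerance = 1e-8)
  }
  eq <- solveEquilibrium(univariateTruth(0.5, 0.2), tol = 1e-12)
  expect_equal(qMatrix(eq)[1, 1], 1.1270167, tolerance = 1e-6)
})

test_that("equilibrium satisfies its stationarity identity", {
  for (truth in list(fullFeatureTruth(), verticalTruth())) {
    eq <- solveEquilibrium(truth, tol = 1e-12)
    G4 <- eq@gamma
    expect_lt(max(abs(eq@QG - (diag(4) + 0.5 * (G4 + t(G4))))), 1e-9)
    expect_lt(max(abs(eq@QG - t(eq@QG))), 1e-12)
    expect_gt(min(eigen(eq@QG, symmetric = TRUE)$values), 0)
    expect_gt(min(eigen(eq@vpM, symmetric = TRUE)$values), 0)
  }
})

test_that("bivariate assortment induces positive q off-diagonals", {
  m <- ntfModel("ABDSTE", sexEqual = TRUE,
                values = c(a_m_11 = 0.7, a_m_21 = 0, a_m_22 = 0.7,
                           mu_11 = 0.10, mu_12 = 0.05, mu_21 = 0.05,
                           mu_22 = 0.10),
                drop = c("b", "d", "s", "t"))
  q <- qMatrix(solveEquilibrium(m))
  expect_gt(q[1, 2], 0)
  expect_gt(q[1, 1], 1)
})

test_that("q diagonal is monotone in the matching copath", {
  mus <- c(0, 0.05, 0.1, 0.15, 0.2)
  q11 <- vapply(mus, function(mu)
    qMatrix(solveEquilibrium(univariateTruth(0.5, mu)))[1, 1], numeric(1))
  expect_true(all(diff(q11) > 0))
})

test_that("inadmissible assortment raises a structured error", {
  # 4 a^2 mu > 1: no real fixed point, iteration must not silently clamp
  expect_error(solveEquilibrium(univariateTruth(0.9, 0.4), maxIter = 500L),
               class = "ntfInadmissible")
})

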