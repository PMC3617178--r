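test_that("random-mating blocks reduce to the classical twin forms", {
  # equal paths across sex, no B, no assortment
  m <- ntfModel("ABDSTE", sexEqual = TRUE,
                values = c(a_m_11 = 0.7, a_m_21 = 0.1, a_m_22 = 0.65,
                           d_m_11 = 0.4, d_m_21 = 0.05, d_m_22 = 0.3,
                           s_m_11 = 0.3, s_m_21 = 0.0, s_m_22 = 0.2,
                           t_m_11 = 0.2, t_m_21 = 0.0, t_m_22 = 0.15,
                           e_m_11 = 0.45, e_m_21 = 0.02, e_m_22 = 0.5),
                drop = "mu")
  eq <- solveEquilibrium(m)
  a <- pathMatrix(m, "a_m"); d <- pathMatrix(m, "d_m")
  s <- pathMatrix(m, "s_m"); tt <- pathMatrix(m, "t_m")
  MZ <- pairCovariance(m, eq, "MZ", "m", "m")
  DZ <- pairCovariance(m, eq, "DZ", "m", "m")
  sib <- pairCovariance(m, eq, "sib", "m", "m")
  # DZ genetic part = a a' / 2 at q = I, Gamma = 0
  expect_equal(DZ, 0.5 * tcrossprod(a) + 0.25 * tcrossprod(d) +
                 tcrossprod(s) + tcrossprod(tt), tolerance = 1e-12)
  # classical identity: MZ - DZ = a a'/2 + 3/4 d d' + t-environment excess
  expect_equal(MZ - DZ, 0.5 * tcrossprod(a) + 0.75 * tcrossprod(d),
               tolerance = 1e-12)
  # siblings differ from DZ twins only by the twin environment
  expect_equal(DZ - sib, tcrossprod(tt), tolerance = 1e-12)
  # parent-offspring at random mating: a a' / 2
  po <- pairCovariance(m, eq, "parent_offspring", "f", "m")
  expect_equal(po, 0.5 * tcrossprod(a), tolerance = 1e-12)
  # spouses are uncorrelated
  expect_true(all(pairCovariance(m, eq, "spouse", "m", "f") == 0))
})

test_that("opposite-sex sharing is attenuated by the cross-sex correlations", {
  truth <- fullFeatureTruth()
  eq <- solveEquilibrium(truth)
  ss <- pairCovariance(truth, eq, "DZ", "m", "m")
  os <- pairCovariance(truth, eq, "DZ", "m", "f")
  # with sex-equal paths in truth for a, the difference comes from rD/rS/rT
  d <- pathMatrix(truth, "d_m"); d2 <- pathMatrix(truth, "d_f")
  s <- pathMatrix(truth, "s_m"); s2 <- pathMatrix(truth, "s_f")
  tt <- pathMatrix(truth, "t_m"); tt2 <- pathMatrix(truth, "t_f")
  manual <- ss - 0.25 * tcrossprod(d) - tcrossprod(s) - tcrossprod(tt) +
    0.9 * 0.25 * tcrossprod(d, d2) + 0.95 * tcrossprod(s, s2) +
    0.9 * tcrossprod(tt, tt2)
  # replace the genetic block: male side keeps B loading, female side loses it
  Ksib <- 0.5 * eq@QG + 0.25 * (eq@gamma + t(eq@gamma))
  Lm <- cbind(pathMatrix(truth, "a_m"), pathMatrix(truth, "b"))
  Lf <- cbind(pathMatrix(truth, "a_f"), matrix(0, 2, 2))
  manual <- manual - Lm %*% Ksib %*% t(Lm) + Lm %*% Ksib %*% t(Lf)
  expect_equal(os, manual, tolerance = 1e-12)
})

test_that("family moment matrices are symmetric PSD compositions of blocks", {
  truth <- fullFeatureTruth()
  eq <- solveEquilibrium(truth)
  cfg <- familyConfiguration(
    c("father", "mother", "twin1", "twin2", "sib1", "sib2"),
    c("m", "f", "f", "f", "m", "f"), "MZ")
  mom <- familyMoments(truth, eq, cfg)
  expect_equal(dim(mom$sigma), c(12, 12))
  expect_lt(max(abs(mom$sigma - t(mom$sigma))), 1e-12)
  expect_gt(min(eigen(mom$sigma, symmetric = TRUE)$values), 0)
  # twin-twin block equals the pair covariance
  expect_equal(mom$sigma[5:6, 7:8],
               unname(pairCovariance(truth, eq, "MZ", "f", "f")),
               ignore_attr = TRUE)
  # father-twin block is the transposed offspring-parent block
  expect_equal(mom$sigma[1:2, 5:6],
               t(pairCovariance(truth, eq, "parent_offspring", "f", "m")),
               ignore_attr = TRUE)
  # singleton family reduces to the phenotypic covariance
  solo <- familyMoments(truth, eq,
                        familyConfiguration("sib1", "m"))
  expect_equal(solo$sigma, phenotypicCov(eq, "m"), ignore_attr = TRUE)
})

test_that("swapping same-sex twin labels permutes the family matrix", {
  truth <- fullFeatureTruth()
  eq <- solveEquilibrium(truth)
  cfg <- familyConfiguration(c("father", "mother", "twin1", "twin2"),
                             c("m", "f", "m", "m"), "DZ")
  mom <- familyMoments(truth, eq, cfg)
  p <- c(1, 2, 4, 3)   # swap twins
  idx <- as.vector(rbind(2 * p - 1, 2 * p))
  expect_equal(unname(mom$sigma[idx, idx]), unname(mom$sigma),
               tolerance = 1e-12)
})

test_that("configuration validation rejects malformed families", {
  expect_error(familyConfiguration(character(0), character(0)), "at least one")
  expect_error(familyConfiguration(c("sib1", "sib1"), c("m", "m")), "unique")
  expect_error(familyConfiguration(c("twin1", "twin2"), c("m", "f"), "MZ"),
               "equal sexes")
  expect_error(familyConfiguration("twin1", "m", "none"), "zygosity")
  expect_error(familyConfiguration("father", "f"), "male")
  expect_error(familyConfiguration("uncle", "m"), "unknown role")
})
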