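test_that("simulation is deterministic given config and seed", {
  truth <- ntfTruthPreset("studylike_sexeq")
  pop1 <- simulatePopulation(truth, n = 2000, generations = 3, seed = 7)
  pop2 <- simulatePopulation(truth, n = 2000, generations = 3, seed = 7)
  expect_identical(pop1$father$P, pop2$father$P)
  d <- allTypesDesign(20)
  f1 <- simulateFamilies(pop1, d, seed = 9)
  f2 <- simulateFamilies(pop2, d, seed = 9)
  expect_identical(f1, f2)
  o1 <- applyObservationModel(f1, seed = 5)
  o2 <- applyObservationModel(f2, seed = 5)
  expect_identical(o1, o2)
  expect_error(simulatePopulation(truth, n = 2000, generations = 3),
               "seed")
})

test_that("latent conservation laws hold in the generated records", {
  truth <- fullFeatureTruth()
  pop <- simulatePopulation(truth, n = 2000, generations = 3, seed = 31)
  fam <- simulateFamilies(pop, allTypesDesign(400), seed = 32,
                          truthRecords = TRUE)
  tr <- attr(fam, "truth")
  key <- paste(fam$family_id, fam$role)
  tkey <- paste(tr$family_id, tr$role)
  expect_identical(key, tkey)
  # observed trait is exactly the path-weighted sum of the stored latents
  mats <- ntfam:::.model_mats(truth)
  G <- as.matrix(tr[, c("A1", "A2", "B1", "B2")])
  rebuild <- function(sex) {
    G %*% t(if (sex == "m") mats$Lm else mats$Lf) +
      as.matrix(tr[, c("D1", "D2")]) %*% t(mats$d[[sex]]) +
      as.matrix(tr[, c("S1", "S2")]) %*% t(mats$s[[sex]]) +
      as.matrix(tr[, c("T1", "T2")]) %*% t(mats$t[[sex]]) +
      as.matrix(tr[, c("E1", "E2")]) %*% t(mats$e[[sex]]) +
      as.matrix(tr[, c("F1", "F2")]) +
      as.matrix(tr[, c("C1", "C2")]) %*% t(mats$c[[sex]])
  }
  P <- rebuild("f")
  male <- fam$sex == "m"
  P[male, ] <- rebuild("m")[male, ]
  expect_lt(max(abs(P - as.matrix(fam[, c("trait1", "trait2")]))), 1e-12)
  # MZ co-twins carry identical A, B and D scores; sibling environments
  # are identical across same-sex sibs; unique environments are not shared
  mz <- fam$zygosity == "MZ"
  t1 <- tr[mz & fam$role == "twin1", ]; t2 <- tr[mz & fam$role == "twin2", ]
  expect_lt(max(abs(as.matrix(t1[, c("A1", "A2", "B1", "B2", "D1", "D2")]) -
                      as.matrix(t2[, c("A1", "A2", "B1", "B2", "D1", "D2")]))),
            1e-12)
  expect_lt(max(abs(t1$S1 - t2$S1)), 1e-12)
  expect_gt(stats::sd(t1$E1 - t2$E1), 0.5)
  expect_lt(abs(cor(t1$E1, t2$E1)), 4 / sqrt(nrow(t1)))
})

test_that("MZ pairs with no unique environment are identical", {
  m <- ntfModel("ABDSTE", sexEqual = TRUE,
                values = c(a_m_11 = 0.7, a_m_21 = 0.1, a_m_22 = 0.7,
                           d_m_11 = 0.4, d_m_21 = 0, d_m_22 = 0.4,
                           s_m_11 = 0.3, s_m_21 = 0, s_m_22 = 0.3,
                           t_m_11 = 0.3, t_m_21 = 0, t_m_22 = 0.3,
                           mu_11 = 0.1, mu_12 = 0, mu_21 = 0, mu_22 = 0.1),
                fix = list(e_m_11 = 0, e_m_21 = 0, e_m_22 = 0,
                           e_f_11 = 0, e_f_21 = 0, e_f_22 = 0))
  pop <- simulatePopulation(m, n = 1500, generations = 2, seed = 41)
  fam <- simulateFamilies(pop, data.frame(sample = "S", type = "MZM",
                                          n = 200, nSibs = 0,
                                          parents = FALSE), seed = 42)
  t1 <- fam[fam$role == "twin1", ]; t2 <- fam[fam$role == "twin2", ]
  expect_lt(max(abs(t1$trait1 - t2$trait1)), 1e-12)
  expect_lt(max(abs(t1$trait2 - t2$trait2)), 1e-12)
})

test_that("the latent additive trajectory reaches a stationary state", {
  truth <- univariateTruth(0.5, 0.2)
  pop <- simulatePopulation(truth, n = 30000, generations = 12, seed = 51)
  q11 <- vapply(pop$trajectory, function(M) M[1, 1], numeric(1))
  # Cauchy criterion: the last two generations agree within 4 MC SEs
  se <- sqrt(2 / 30000) * q11[12]
  expect_lt(abs(q11[12] - q11[11]), 4 * sqrt(2) * se)
  closed <- (1 - sqrt(1 - 4 * 0.5 * 0.2)) / (2 * 0.5 * 0.2)
  expect_lt(abs(q11[12] - closed), 4 * se)
  # random mating keeps the latent variance at one in every generation
  pop0 <- simulatePopulation(univariateTruth(0.5, 0), n = 30000,
                             generations = 5, seed = 52)
  q0 <- vapply(pop0$trajectory, function(M) M[1, 1], numeric(1))
  expect_true(all(abs(q0 - 1) < 4 * sqrt(2 / 30000)))
  expect_true(all(abs(pop0$spousalCov) < 4 / sqrt(30000)))
})

test_that("homogamy couples phenotypes without disturbing the gene pool", {
  truth <- homogamyTruth()
  pop <- simulatePopulation(truth, n = 40000, generations = 5, seed = 61)
  target <- tcrossprod(pathMatrix(truth, "c_m"), pathMatrix(truth, "c_f"))
  expect_lt(max(abs(pop$spousalCov - target)), 4 * 1.5 / sqrt(40000))
  q <- pop$trajectory[[5]]
  expect_lt(max(abs(q - diag(2))), 4 * sqrt(2 / 40000) * 1.5)
})

test_that("the observation model injects ages, scales, outliers, missingness", {
  truth <- ntfTruthPreset("studylike_sexeq")
  pop <- simulatePopulation(truth, n = 2000, generations = 3, seed = 71)
  fam <- simulateFamilies(pop, allTypesDesign(150), seed = 72)
  cfg <- obsModelConfig(outlierRate = 0.002,
                        exactOutliers = list(trait = "trait2", neg = 8,
                                             pos = 2),
                        missingRate = c(twin = 0.02, sib = 0.05,
                                        parent = 0.1))
  raw <- applyObservationModel(fam, cfg, seed = 73)
  # ages live in role-specific ranges and co-twins share one age
  rc <- ntfam:::.role_class(raw$role)
  expect_true(all(raw$age[rc == "twin"] >= 12 & raw$age[rc == "twin"] <= 28))
  expect_true(all(raw$age[rc == "parent"] >= 29))
  t1 <- raw[raw$role == "twin1", ]; t2 <- raw[raw$role == "twin2", ]
  expect_identical(t1$age, t2$age[match(t1$family_id, t2$family_id)])
  # IQ-like scale
  expect_gt(mean(raw$trait1, na.rm = TRUE), 90)
  expect_lt(mean(raw$trait1, na.rm = TRUE), 120)
  # exact outliers: 8 low + 2 high beyond 4 SD, all in trait2
  olog <- attr(raw, "outlierLog")
  h <- olog[olog$trait == "trait2", ]
  expect_gte(h$count[h$sign == "neg"], 8)
  expect_gte(h$count[h$sign == "pos"], 2)
  z2 <- scale(raw$trait2)
  expect_gte(sum(z2 < -4, na.rm = TRUE), 8)
  expect_gte(sum(z2 > 4, na.rm = TRUE), 2)
  expect_gt(sum(is.na(raw$trait1)), 0)
  # rate-based injection is binomial by construction
  raw2 <- applyObservationModel(fam, obsModelConfig(outlierRate = 0.01),
                                seed = 74)
  o2 <- attr(raw2, "outlierLog")
  n2 <- sum(o2$count)
  expect_gt(n2, stats::qbinom(0.0005, nrow(fam) * 2, 0.01))
  expect_lt(n2, stats::qbinom(0.9995, nrow(fam) * 2, 0.01))
})

test_that("sample templates control which relatives appear", {
  fx <- studyFixture(seed = 301, scale = 0.08, nPop = 2000,
                      generations = 3)
  expect_true(all(c("LTS", "CTS", "FAM", "QIMR") %in% fx$sample))
  # community samples carry no parental rows; the family sample no twins
  expect_equal(sum(fx$sample == "CTS" &
                     fx$role %in% c("father", "mother")), 0)
  expect_equal(sum(fx$sample == "QIMR" &
                     fx$role %in% c("father", "mother")), 0)
  expect_gt(sum(fx$sample == "LTS" & fx$role == "father"), 0)
  expect_equal(sum(fx$sample == "FAM" &
                     fx$role %in% c("twin1", "twin2")), 0)
  expect_gt(sum(fx$sample == "FAM" & fx$role == "father"), 0)
})
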