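makeRow <- function(fid, role, sex, zyg, t1, t2, sample = "S") {
  data.frame(family_id = fid, role = role, sex = sex, zygosity = zyg,
             age = NA_real_, sample = sample, trait1 = t1, trait2 = t2,
             stringsAsFactors = FALSE)
}

test_that("a standard-normal singleton contributes log(2 pi)", {
  m <- univariateTruth(0.5, 0)   # unit phenotypic variance, mean zero
  d <- makeRow("f1", "sib1", "m", "none", 0, NA)
  expect_equal(as.numeric(fimlNegLogLik(m, d)), log(2 * pi),
               tolerance = 1e-12)
  # and the quadratic form appears for a nonzero score
  d2 <- makeRow("f1", "sib1", "m", "none", 1.3, NA)
  expect_equal(as.numeric(fimlNegLogLik(m, d2)), log(2 * pi) + 1.3^2,
               tolerance = 1e-12)
})

test_that("complete-data likelihood equals a dense multivariate-normal oracle", {
  truth <- fullFeatureTruth()
  eq <- solveEquilibrium(truth)
  fam <- simulateSmall(truth, nFam = 40L)
  val <- as.numeric(fimlNegLogLik(truth, fam))
  # independent dense evaluation: base determinant + solve, per family
  oracle <- 0
  for (fid in unique(fam$family_id)) {
    fr <- fam[fam$family_id == fid, ]
    ord <- order(match(fr$role, c("father", "mother", "twin1", "twin2",
                                  paste0("sib", 1:9))))
    fr <- fr[ord, ]
    zyg <- if (any(fr$role %in% c("twin1", "twin2")))
      fr$zygosity[fr$role %in% c("twin1", "twin2")][1] else "none"
    cfg <- familyConfiguration(fr$role, fr$sex, zyg)
    S <- familyMoments(truth, eq, cfg)$sigma
    y <- as.vector(rbind(fr$trait1, fr$trait2))
    oracle <- oracle + length(y) * log(2 * pi) +
      determinant(S, logarithm = TRUE)$modulus +
      drop(t(y) %*% solve(S, y))
  }
  expect_equal(val, as.numeric(oracle), tolerance = 1e-8)
})

test_that("fully missing members marginalise out exactly", {
  truth <- fullFeatureTruth()
  # every configuration: parents, twins of each zygosity, extra sibs
  configs <- list(
    list(roles = c("father", "mother", "twin1", "twin2"),
         sexes = c("m", "f", "m", "m"), zyg = "MZ"),
    list(roles = c("father", "mother", "twin1", "twin2", "sib1"),
         sexes = c("m", "f", "m", "f", "f"), zyg = "DZ"),
    list(roles = c("mother", "sib1", "sib2"),
         sexes = c("f", "m", "f"), zyg = "none"),
    list(roles = c("twin1", "twin2", "sib1"),
         sexes = c("f", "f", "m"), zyg = "DZ"))
  set.seed(99)
  for (cf in configs) {
    k <- length(cf$roles)
    vals <- matrix(rnorm(2 * k), k, 2)
    for (dropIdx in seq_len(k)) {
      full <- makeRow(paste0("f", dropIdx), cf$roles, cf$sexes,
                      ifelse(cf$roles %in% c("twin1", "twin2"), cf$zyg,
                             "none"),
                      vals[, 1], vals[, 2])
      withMissing <- full
      withMissing$trait1[dropIdx] <- NA
      withMissing$trait2[dropIdx] <- NA
      deleted <- full[-dropIdx, ]
      # deleting twin1 from a DZ family leaves twin2 as a lone twin; keep
      # the zygosity, the configuration machinery accepts partial pairs
      expect_equal(as.numeric(fimlNegLogLik(truth, withMissing)),
                   as.numeric(fimlNegLogLik(truth, deleted)),
                   tolerance = 1e-10)
    }
  }
})

test_that("families with no observations are dropped and counted", {
  truth <- fullFeatureTruth()
  d <- rbind(makeRow("f1", "sib1", "m", "none", 0.5, 0.2),
             makeRow("f2", "sib1", "m", "none", NA, NA))
  v <- fimlNegLogLik(truth, d)
  expect_equal(attr(v, "nDroppedEmpty"), 1L)
  d1 <- makeRow("f1", "sib1", "m", "none", 0.5, 0.2)
  expect_equal(as.numeric(v), as.numeric(fimlNegLogLik(truth, d1)))
})

test_that("likelihood is invariant to row order (grouping contract)", {
  truth <- fullFeatureTruth()
  fam <- simulateSmall(truth, nFam = 30L)
  set.seed(3)
  shuffled <- fam[sample(nrow(fam)), ]
  expect_equal(as.numeric(fimlNegLogLik(truth, fam)),
               as.numeric(fimlNegLogLik(truth, shuffled)),
               tolerance = 1e-10)
})

test_that("the family-table round-trips through its text format", {
  truth <- fullFeatureTruth()
  fam <- simulateSmall(truth, nFam = 15L)
  fam$trait1[3] <- NA
  path <- tempfile(fileext = ".tsv")
  writeFamilyTable(fam, path)
  back <- readFamilyTable(path)
  expect_equal(back$trait1, fam$trait1, tolerance = 1e-12)
  expect_identical(back$role, fam$role)
  expect_error(validateFamilyTable(fam[, -1]), "missing column")
})
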