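test_that("mode gates which matrices are active", {
  ste <- ntfModel("ABDSTE")
  fte <- ntfModel("ABDFTE")
  cte <- ntfModel("ABDCTE")
  expect_true(all(c("s_m", "s_f", "mu") %in% ste@params$mat))
  expect_false(any(grepl("^v_", ste@params$mat)))
  # F-model: no sibling-environment matrices, vertical transmission free
  expect_false(any(c("s_m", "s_f") %in% fte@params$mat))
  expect_true(all(c("v_fs", "v_fd", "v_ms", "v_md") %in% fte@params$mat))
  # homogamy: no copaths, family environment free
  expect_false("mu" %in% cte@params$mat)
  expect_true(all(c("c_m", "c_f") %in% cte@params$mat))
  expect_true(all(cte@params$free[cte@params$mat %in% c("c_m", "c_f")]))
})

test_that("free-parameter counts follow structural edits", {
  full <- ntfModel("ABDSTE")
  k <- nFreeParams(full)
  expect_equal(k, 40)  # 11 lower-tri matrices + 4 copaths + 3 correlations
  expect_equal(k - nFreeParams(reduceModel(full, drop = "t")), 6)
  expect_equal(k - nFreeParams(reduceModel(full, drop = "b")), 3)
  expect_equal(k - nFreeParams(reduceModel(full, fix = list(r_S = 1))), 1)
  expect_equal(
    k - nFreeParams(reduceModel(full, equate = list(c("mu_12", "mu_21")))), 1)
  expect_equal(
    k - nFreeParams(reduceModel(full, fix = list(a_m_21 = 0, a_f_21 = 0))), 2)
  # the q off-diagonal constraint costs one effective parameter
  expect_equal(k - nFreeParams(reduceModel(full, constrainQ = TRUE)), 1)
})

test_that("edits validate their targets", {
  m <- ntfModel("ABDSTE")
  expect_error(reduceModel(m, drop = "v"), "inactive")
  expect_error(reduceModel(m, fix = list(v_fs_11 = 0.1)), "unknown")
  expect_error(reduceModel(m, fix = list(a_m_11 = -0.5)), "negative")
  expect_error(reduceModel(m, equate = list(c("mu_12", "nope"))), "unknown")
  expect_error(ntfModel("ABDSTE", values = c(zzz = 1)), "unknown")
})

test_that("validity enforces triangularity, bounds and S/F exclusion", {
  m <- ntfModel("ABDSTE")
  bad <- m
  bad@params$value[bad@params$param == "r_D"] <- 1.5
  expect_error(validObject(bad), "correlations")
  bad2 <- m
  i <- which(bad2@params$param == "a_m_21")
  bad2@params$i[i] <- 1L; bad2@params$j[i] <- 2L
  bad2@params$value[i] <- 0.3
  expect_error(validObject(bad2), "upper-triangular")
  bad3 <- m
  bad3@params$mat[bad3@params$mat == "t_m"] <- "v_fs"
  expect_error(validObject(bad3), "not identified")
})

test_that("sex-equating halves the path registry and removes sex limitation", {
  m <- ntfModel("ABDSTE", sexEqual = TRUE)
  # a, d, s, t, e equated (5 x 3), mu free (4); b dropped, r's fixed at 1
  expect_equal(nFreeParams(m), 19)
  expect_identical(pathMatrix(m, "a_m"), pathMatrix(m, "a_f"))
  expect_true(all(pathMatrix(m, "b") == 0))
})

test_that("theta packing round-trips through the registry", {
  m <- ntfModel("ABDSTE", equate = list(c("mu_12", "mu_21")))
  th <- ntfam:::.pack_theta(m)
  th2 <- th + seq_along(th) * 1e-3
  m2 <- ntfam:::.unpack_theta(m, th2)
  expect_equal(as.numeric(ntfam:::.pack_theta(m2)), as.numeric(th2))
  # equated cells move together
  expect_equal(ntfam:::.get_mat(m2, "mu")[1, 2],
               ntfam:::.get_mat(m2, "mu")[2, 1])
})
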