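# Shared fixtures: truth parameter sets, designs and fitting controls used
# across the test files.  Everything is generated in code; sizes are kept
# small enough for routine runs while leaving Monte-Carlo error well inside
# the 4-SE oracle tolerance.

# A deliberately "everything on" phenotypic-assortment truth: sex-specific
# paths, male-specific B, cross-sex correlations below 1, twin environment.
fullFeatureTruth <- function() {
  ntfModel("ABDSTE", values = c(
    a_m_11 = 0.74, a_m_21 = 0.09, a_m_22 = 0.78,
    a_f_11 = 0.74, a_f_21 = 0.09, a_f_22 = 0.78,
    b_11 = 0.15, b_21 = 0.02, b_22 = 0.15,
    d_m_11 = 0.38, d_m_21 = 0.03, d_m_22 = 0.40,
    d_f_11 = 0.30, d_f_21 = 0.02, d_f_22 = 0.32,
    s_m_11 = 0.28, s_m_21 = 0.00, s_m_22 = 0.10,
    s_f_11 = 0.30, s_f_21 = 0.00, s_f_22 = 0.10,
    t_m_11 = 0.15, t_m_21 = 0.00, t_m_22 = 0.12,
    t_f_11 = 0.15, t_f_21 = 0.00, t_f_22 = 0.12,
    e_m_11 = 0.42, e_m_21 = 0.02, e_m_22 = 0.35,
    e_f_11 = 0.40, e_f_21 = 0.02, e_f_22 = 0.30,
    mu_11 = 0.30, mu_12 = 0.10, mu_21 = 0.06, mu_22 = 0.17,
    r_D = 0.9, r_S = 0.95, r_T = 0.9))
}

homogamyTruth <- function() {
  ntfModel("ABDCTE", values = c(
    a_m_11 = 0.70, a_m_21 = 0.08, a_m_22 = 0.75,
    a_f_11 = 0.70, a_f_21 = 0.08, a_f_22 = 0.75,
    b_11 = 0.10, b_21 = 0.00, b_22 = 0.10,
    d_m_11 = 0.30, d_m_21 = 0.02, d_m_22 = 0.30,
    d_f_11 = 0.30, d_f_21 = 0.02, d_f_22 = 0.30,
    c_m_11 = 0.35, c_m_21 = 0.05, c_m_22 = 0.25,
    c_f_11 = 0.33, c_f_21 = 0.05, c_f_22 = 0.27,
    t_m_11 = 0.15, t_m_21 = 0.00, t_m_22 = 0.12,
    t_f_11 = 0.15, t_f_21 = 0.00, t_f_22 = 0.12,
    e_m_11 = 0.45, e_m_21 = 0.02, e_m_22 = 0.40,
    e_f_11 = 0.45, e_f_21 = 0.02, e_f_22 = 0.40,
    r_D = 0.9, r_T = 0.9))
}

verticalTruth <- function() {
  ntfModel("ABDFTE", values = c(
    a_m_11 = 0.70, a_m_21 = 0.08, a_m_22 = 0.75,
    a_f_11 = 0.70, a_f_21 = 0.08, a_f_22 = 0.75,
    b_11 = 0.10, b_21 = 0.00, b_22 = 0.10,
    d_m_11 = 0.30, d_m_21 = 0.02, d_m_22 = 0.30,
    d_f_11 = 0.30, d_f_21 = 0.02, d_f_22 = 0.30,
    t_m_11 = 0.15, t_m_21 = 0.00, t_m_22 = 0.12,
    t_f_11 = 0.15, t_f_21 = 0.00, t_f_22 = 0.12,
    e_m_11 = 0.45, e_m_21 = 0.02, e_m_22 = 0.40,
    e_f_11 = 0.45, e_f_21 = 0.02, e_f_22 = 0.40,
    v_fs_11 = 0.12, v_fs_12 = 0.02, v_fs_21 = 0.01, v_fs_22 = 0.08,
    v_fd_11 = 0.10, v_fd_12 = 0.02, v_fd_21 = 0.01, v_fd_22 = 0.09,
    v_ms_11 = 0.14, v_ms_12 = 0.01, v_ms_21 = 0.02, v_ms_22 = 0.07,
    v_md_11 = 0.11, v_md_12 = 0.02, v_md_21 = 0.01, v_md_22 = 0.10,
    mu_11 = 0.15, mu_12 = 0.05, mu_21 = 0.03, mu_22 = 0.10,
    r_D = 0.9, r_T = 0.9))
}

# univariate embedding: trait2 carries no paths at all
univariateTruth <- function(a2 = 0.5, mu = 0.2) {
  ntfModel("ABDSTE",
           values = c(a_m_11 = sqrt(a2), a_f_11 = sqrt(a2),
                      e_m_11 = sqrt(1 - a2), e_f_11 = sqrt(1 - a2),
                      mu_11 = mu),
           drop = c("b", "d", "s", "t"),
           fix = list(a_m_21 = 0, a_m_22 = 0, a_f_21 = 0, a_f_22 = 0,
                      e_m_21 = 0, e_m_22 = 0, e_f_21 = 0, e_f_22 = 0,
                      mu_12 = 0, mu_21 = 0, mu_22 = 0,
                      r_D = 1, r_S = 1, r_T = 1))
}

# all family configurations in one design
allTypesDesign <- function(n, nSibs = 1, parents = TRUE) {
  data.frame(sample = "SIM",
             type = c("MZM", "MZF", "DZM", "DZF", "DZOS", "SIB"),
             n = n, nSibs = c(nSibs, nSibs, nSibs, nSibs, nSibs,
                              max(2, nSibs)),
             parents = parents)
}

quickControl <- function() list(iter.max = 400L, eval.max = 1600L,
                                rel.tol = 1e-9)

# small simulated data set under a given truth, cached per session
simulateSmall <- function(truth, nFam = 250L, seedPop = 11L, seedFam = 12L,
                          nPop = 6000L, generations = 10L) {
  pop <- simulatePopulation(truth, n = nPop, generations = generations,
                            seed = seedPop)
  simulateFamilies(pop, allTypesDesign(nFam), seed = seedFam)
}
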