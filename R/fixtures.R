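# Deterministic truth presets and the bundled synthetic study fixture.

#' Truth presets for simulation studies
#'
#' Named generating parameter sets used throughout the package's tests and
#' reproduction script:
#' \describe{
#'   \item{studylike}{full sex-specific ABDSTE regime calibrated so the
#'     implied relative correlations mirror a large twin-family study of
#'     IQ-like and height-like traits: MZ about .82-.90, DZ/sib about
#'     .44-.51, spousal within-trait about .33/.18, spousal cross-trait
#'     about .08/.15, within-person cross-trait about .10-.12, narrow
#'     heritabilities .60-.75.  T and B are zero in truth (so the reduction
#'     ladder should drop them) and cross-sex correlations are 1.}
#'   \item{studylike_sexeq}{sex-equated ADSE + copath version of the same
#'     regime, used for reduced-scale recovery studies.}
#'   \item{homogamy}{sex-equated ABDCTE regime: spousal resemblance from a
#'     shared couple environment, random mating with respect to phenotype.}
#'   \item{pleiotropy_only}{phenotypic-assortment regime with sex-specific
#'     additive paths whose cross-trait genetic covariance comes only from
#'     pleiotropic paths (diagonal copath matrix).  Discriminating
#'     pleiotropy from gametic phase disequilibrium relies on the
#'     sex-specific additive structure: the equilibrium q matrix is shared
#'     across sexes while the Cholesky cross paths are not, so the two
#'     sources are not interchangeable (see
#'     \code{\link{discriminationModel}}).}
#'   \item{assortment_only}{the reverse: no pleiotropic paths, cross-trait
#'     genetic covariance only from cross-trait assortment, with cross
#'     copaths at the level of the spousal cross-correlations large studies
#'     report (about .1-.2).}
#' }
#'
#' @param name preset name.
#' @return an \code{NTFModel} holding the truth values.
#' @export
ntfTruthPreset <- function(name = c("studylike", "studylike_sexeq",
                                    "homogamy", "pleiotropy_only",
                                    "assortment_only")) {
  name <- match.arg(name)
  if (name == "studylike") {
    vals <- c(
      a_m_11 = 0.71, a_m_21 = 0.05, a_m_22 = 0.73,
      a_f_11 = 0.73, a_f_21 = 0.06, a_f_22 = 0.77,
      d_m_11 = 0.39, d_m_21 = 0.00, d_m_22 = 0.45,
      d_f_11 = 0.32, d_f_21 = 0.00, d_f_22 = 0.35,
      s_m_11 = 0.27, s_m_21 = 0.00, s_m_22 = 0.10,
      s_f_11 = 0.31, s_f_21 = 0.00, s_f_22 = 0.10,
      e_m_11 = 0.451, e_m_21 = 0.03, e_m_22 = 0.364,
      e_f_11 = 0.432, e_f_21 = 0.03, e_f_22 = 0.316,
      mu_11 = 0.30, mu_12 = 0.025, mu_21 = 0.10, mu_22 = 0.175)
    return(ntfModel("ABDSTE", values = vals, drop = c("b", "t"),
                    fix = list(r_D = 1, r_S = 1, r_T = 1)))
  }
  if (name == "studylike_sexeq") {
    vals <- c(
      a_m_11 = 0.72, a_m_21 = 0.055, a_m_22 = 0.75,
      d_m_11 = 0.36, d_m_21 = 0.00, d_m_22 = 0.40,
      s_m_11 = 0.29, s_m_21 = 0.00, s_m_22 = 0.10,
      e_m_11 = 0.44, e_m_21 = 0.03, e_m_22 = 0.34,
      mu_11 = 0.30, mu_12 = 0.025, mu_21 = 0.10, mu_22 = 0.175)
    return(ntfModel("ABDSTE", sexEqual = TRUE, values = vals,
                    drop = "t", fix = list()))
  }
  if (name == "homogamy") {
    vals <- c(
      a_m_11 = 0.72, a_m_21 = 0.055, a_m_22 = 0.75,
      d_m_11 = 0.36, d_m_21 = 0.00, d_m_22 = 0.40,
      c_m_11 = 0.33, c_m_21 = 0.05, c_m_22 = 0.26,
      e_m_11 = 0.44, e_m_21 = 0.03, e_m_22 = 0.34)
    return(ntfModel("ABDCTE", sexEqual = TRUE, values = vals, drop = "t"))
  }
  if (name == "pleiotropy_only") {
    vals <- c(
      a_m_11 = 0.71, a_m_21 = 0.10, a_m_22 = 0.73,
      a_f_11 = 0.73, a_f_21 = 0.11, a_f_22 = 0.77,
      d_m_11 = 0.36, d_m_21 = 0.00, d_m_22 = 0.40,
      s_m_11 = 0.29, s_m_21 = 0.00, s_m_22 = 0.10,
      e_m_11 = 0.44, e_m_21 = 0.03, e_m_22 = 0.34,
      mu_11 = 0.30, mu_12 = 0, mu_21 = 0, mu_22 = 0.175)
    return(discriminationModel(vals))
  }
  # assortment_only
  vals <- c(
    a_m_11 = 0.71, a_m_21 = 0.00, a_m_22 = 0.73,
    a_f_11 = 0.73, a_f_21 = 0.00, a_f_22 = 0.77,
    d_m_11 = 0.36, d_m_21 = 0.00, d_m_22 = 0.40,
    s_m_11 = 0.29, s_m_21 = 0.00, s_m_22 = 0.10,
    e_m_11 = 0.44, e_m_21 = 0.00, e_m_22 = 0.34,
    mu_11 = 0.30, mu_12 = 0.15, mu_21 = 0.15, mu_22 = 0.175)
  discriminationModel(vals)
}

#' Model class used by the pleiotropy / gametic-phase-disequilibrium
#' discrimination studies
#'
#' Sex-specific additive paths (the structure whose shared equilibrium q
#' but per-sex Cholesky cross paths make pleiotropy and gametic phase
#' disequilibrium distinguishable) with the nuisance matrices d, s, e
#' equated across the sexes; B and T dropped, cross-sex correlations fixed
#' at 1.
#'
#' @param values optional named starting/truth values (male-matrix names).
#' @return an \code{NTFModel}.
#' @export
discriminationModel <- function(values = NULL) {
  eqs <- list()
  for (pr in list(c("d_m", "d_f"), c("s_m", "s_f"), c("e_m", "e_f")))
    for (cl in list(c(1L, 1L), c(2L, 1L), c(2L, 2L)))
      eqs <- c(eqs, list(sprintf("%s_%d%d", pr, cl[1], cl[2])))
  ntfModel("ABDSTE", values = values, drop = c("b", "t"),
           fix = list(r_D = 1, r_S = 1, r_T = 1), equate = eqs)
}

#' Family design templates mirroring a four-sample twin-family study
#'
#' Four samples: a longitudinal twin sample with parents (LTS-like), a
#' community twin sample without parents (CTS-like), a family sample of
#' siblings and parents with no twins (FAM-like), and an adolescent twin
#' sample without parents (QIMR-like).  Counts approximate the published
#' per-sample family numbers; \code{scale} multiplies them.
#'
#' @param scale multiplier on family counts.
#' @return a design data.frame for \code{\link{simulateFamilies}}.
#' @export
studyDesign <- function(scale = 1) {
  d <- rbind(
    data.frame(sample = "LTS", type = c("MZM", "MZF", "DZM", "DZF", "DZOS"),
               n = c(102, 112, 91, 97, 30),
               nSibs = c(0, 0, 1, 1, 1), parents = TRUE),
    data.frame(sample = "CTS", type = c("MZM", "MZF", "DZM", "DZF"),
               n = c(205, 259, 266, 271),
               nSibs = c(0, 0, 1, 1), parents = FALSE),
    data.frame(sample = "FAM", type = "SIB", n = 401, nSibs = 2,
               parents = TRUE),
    data.frame(sample = "QIMR", type = c("MZM", "MZF", "DZM", "DZF", "DZOS"),
               n = c(183, 201, 281, 200, 100),
               nSibs = c(1, 0, 0, 0, 1), parents = FALSE))
  d$n <- ceiling(d$n * scale)
  d
}

#' Bundled synthetic study fixture
#'
#' Deterministically generates a raw family table with the structure the
#' analysis pipeline expects: the \code{studylike} truth simulated to
#' mating equilibrium, families drawn per \code{\link{studyDesign}}, and
#' the observation model applied (ages, sex/age covariate effects on
#' IQ-like and height-like raw scales, 10 gross height outliers — 8 low,
#' 2 high — and parental rows absent in the two community samples by
#' design).  All data are synthetic.
#'
#' @param seed RNG seed (one seed drives population, families and
#'   observation).
#' @param scale multiplier on family counts.
#' @param nPop couples per generation in the equilibrium simulation.
#' @param generations generations simulated before families are drawn.
#' @return a raw family table; attributes \code{"truth_model"} (the
#'   generating \code{NTFModel}) and \code{"outlierLog"}.
#' @export
studyFixture <- function(seed = 101L, scale = 1, nPop = 20000L,
                          generations = 15L) {
  truth <- ntfTruthPreset("studylike")
  pop <- simulatePopulation(truth, n = nPop, generations = generations,
                            seed = seed)
  fam <- simulateFamilies(pop, studyDesign(scale), seed = seed + 1L)
  out <- applyObservationModel(
    fam,
    obsModelConfig(exactOutliers = list(trait = "trait2", neg = 8, pos = 2),
                   missingRate = c(twin = 0.02, sib = 0.05, parent = 0.05)),
    seed = seed + 2L)
  attr(out, "truth_model") <- truth
  out
}
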