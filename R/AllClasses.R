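#' @import methods
NULL

#' Nuclear twin family model specification
#'
#' An \code{NTFModel} holds one variant of the bivariate nuclear twin family
#' model: the mode (which latent sources are active and how spousal
#' resemblance is generated), all 2x2 path matrices with their current
#' values, and a registry of free versus fixed cells with box bounds and
#' equality groups.  Trait order is fixed throughout the package as
#' (trait1 = IQ-like, trait2 = height-like).
#'
#' Modes:
#' \describe{
#'   \item{ABDSTE}{primary phenotypic assortment (copath matrix \code{mu});
#'     sibling environment S, twin environment T.}
#'   \item{ABDFTE}{primary phenotypic assortment; vertical transmission F
#'     (parent phenotype to offspring environment) instead of S.  S and F are
#'     not jointly identified, so they are never simultaneously active.}
#'   \item{ABDCTE}{social homogamy: spousal resemblance through a family
#'     environment C shared by spouses and children; \code{mu} is inactive
#'     and treated as zero.}
#' }
#'
#' @slot mode character, one of \code{"ABDSTE"}, \code{"ABDFTE"},
#'   \code{"ABDCTE"}.
#' @slot params data.frame registry with columns \code{param}, \code{mat},
#'   \code{i}, \code{j}, \code{value}, \code{free}, \code{lower},
#'   \code{upper}, \code{group}.
#' @slot constrainQ logical; if \code{TRUE}, fitting restricts the free
#'   parameters to the surface where the equilibrium additive-genetic matrix
#'   q has a zero off-diagonal (one effective constraint against k, used to
#'   test gametic phase disequilibrium).
#' @slot meansModel character, one of \code{"zero"}, \code{"trait"},
#'   \code{"trait_sex"}.
#' @export
setClass("NTFModel",
  representation(
    mode       = "character",
    params     = "data.frame",
    constrainQ = "logical",
    meansModel = "character"
  )
)

.ntf_modes <- c("ABDSTE", "ABDFTE", "ABDCTE")

setValidity("NTFModel", function(object) {
  msgs <- character(0)
  if (!(object@mode %in% .ntf_modes))
    msgs <- c(msgs, sprintf("mode must be one of %s",
                            paste(.ntf_modes, collapse = ", ")))
  need <- c("param", "mat", "i", "j", "value", "free", "lower", "upper",
            "group")
  if (!all(need %in% names(object@params)))
    msgs <- c(msgs, "parameter registry is missing required columns")
  else {
    p <- object@params
    if (anyDuplicated(p$param))
      msgs <- c(msgs, "duplicated parameter names in registry")
    # Cholesky path matrices: lower-triangular with nonnegative diagonals
    tri <- p$mat %in% .cholesky_mats
    bad <- tri & p$i < p$j & p$value != 0
    if (any(bad))
      msgs <- c(msgs, "upper-triangular cells of path matrices must be zero")
    dg <- tri & p$i == p$j & p$value < 0
    if (any(dg))
      msgs <- c(msgs, "path-matrix diagonals must be nonnegative")
    rc <- p$mat == "rcor"
    if (any(rc & (p$value < -1 | p$value > 1)))
      msgs <- c(msgs, "cross-sex correlations must lie in [-1, 1]")
    act <- unique(p$mat)
    if (all(c("s_m", "v_fs") %in% act))
      msgs <- c(msgs, "S and F machinery cannot both be active (not identified)")
  }
  if (!(object@meansModel %in% c("zero", "trait", "trait_sex")))
    msgs <- c(msgs, "meansModel must be 'zero', 'trait' or 'trait_sex'")
  if (length(msgs)) msgs else TRUE
})

.cholesky_mats <- c("a_m", "a_f", "b", "d_m", "d_f", "s_m", "s_f",
                    "t_m", "t_f", "e_m", "e_f", "c_m", "c_f")

#' Equilibrium moments of a nuclear twin family model
#'
#' Stationary latent and phenotypic moments implied by an \code{NTFModel}
#' under its mating regime.  The additive machinery is solved jointly over
#' the stacked latent vector (A, B): \code{QG} is its 4x4 equilibrium
#' covariance, whose leading 2x2 block is the classical q matrix (identity
#' under random mating) and whose trailing block is the male-specific-B
#' analogue; assortment also induces a nonzero A-B cross block.
#'
#' @slot QG 4x4 equilibrium covariance of the stacked (A, B) latents.
#' @slot gamma 4x4 covariance between father's and mother's stacked latents
#'   (rows index the father).
#' @slot wM,wF 4x2 covariance between an individual's stacked latents and
#'   their familial environment F, per sex (zero unless F is active).
#' @slot fvarM,fvarF 2x2 variance of F per sex.
#' @slot vpM,vpF 2x2 model-implied phenotypic covariance per sex.
#' @slot converged logical; \code{nIter} iterations used; \code{residual}
#'   final max-norm fixed-point residual.
#' @export
setClass("NTFEquilibrium",
  representation(
    QG = "matrix", gamma = "matrix",
    wM = "matrix", wF = "matrix",
    fvarM = "matrix", fvarF = "matrix",
    vpM = "matrix", vpF = "matrix",
    converged = "logical", nIter = "integer", residual = "numeric"
  )
)

setValidity("NTFEquilibrium", function(object) {
  msgs <- character(0)
  if (!all(dim(object@QG) == c(4, 4))) msgs <- c(msgs, "QG must be 4x4")
  if (max(abs(object@QG - t(object@QG))) > 1e-8)
    msgs <- c(msgs, "QG must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' Result of a full-information maximum likelihood fit
#'
#' @slot model the fitted \code{NTFModel} with estimates in place.
#' @slot equilibrium the \code{NTFEquilibrium} at the optimum.
#' @slot minus2LL -2 log-likelihood at the optimum.
#' @slot k number of free parameters (equality groups counted once, minus
#'   active equilibrium constraints).
#' @slot converged logical.
#' @slot nEvaluations total objective evaluations across starts.
#' @slot bestStart index of the start that attained the optimum.
#' @slot startDiagnostics per-start data.frame (objective, convergence code).
#' @export
setClass("NTFFit",
  representation(
    model = "NTFModel",
    equilibrium = "NTFEquilibrium",
    minus2LL = "numeric",
    k = "integer",
    converged = "logical",
    nEvaluations = "integer",
    bestStart = "integer",
    startDiagnostics = "data.frame"
  )
)

setValidity("NTFFit", function(object) {
  if (length(object@minus2LL) != 1 || !is.finite(object@minus2LL))
    "minus2LL must be a finite scalar" else TRUE
})

#' Likelihood-ratio test between nested fits
#'
#' @slot chi2 likelihood-ratio statistic (difference in -2 log-likelihood).
#' @slot df difference in free-parameter count.
#' @slot p upper-tail chi-square probability.
#' @slot retained decision at the configured threshold: \code{TRUE} means the
#'   tested parameters are retained (p below threshold, reduction rejected).
#' @slot clamped \code{TRUE} if a tiny negative statistic was clamped to 0.
#' @export
setClass("NTFTest",
  representation(
    chi2 = "numeric", df = "integer", p = "numeric",
    retained = "logical", clamped = "logical"
  )
)

setValidity("NTFTest", function(object) {
  msgs <- character(0)
  if (object@p < 0 || object@p > 1) msgs <- c(msgs, "p must be in [0, 1]")
  if (object@chi2 < 0) msgs <- c(msgs, "chi2 must be nonnegative")
  if (object@df < 1) msgs <- c(msgs, "df must be >= 1")
  if (length(msgs)) msgs else TRUE
})
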