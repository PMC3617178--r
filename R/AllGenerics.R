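#' Extract a 2x2 parameter matrix from a model
#'
#' @param object an \code{NTFModel}.
#' @param name matrix name, e.g. \code{"a_m"}, \code{"mu"}, \code{"v_fs"}.
#' @return a 2x2 numeric matrix (zeros if the matrix is inactive in the
#'   model's mode).
#' @export
setGeneric("pathMatrix", function(object, name) standardGeneric("pathMatrix"))

#' Equilibrium additive-genetic covariance matrix q
#'
#' The 2x2 covariance of the latent additive-genetic factors shared by both
#' sexes at mating equilibrium; the identity matrix under random mating, and
#' inflated by gametic phase disequilibrium under assortment.
#' @param object an \code{NTFEquilibrium}.
#' @export
setGeneric("qMatrix", function(object) standardGeneric("qMatrix"))

#' Equilibrium covariance of the male-specific additive factor B
#' @param object an \code{NTFEquilibrium}.
#' @export
setGeneric("qBMatrix", function(object) standardGeneric("qBMatrix"))

#' Covariance between spouses' latent additive-genetic values (Gamma)
#'
#' Rows index the father's traits, columns the mother's.
#' @param object an \code{NTFEquilibrium}.
#' @export
setGeneric("gammaMatrix", function(object) standardGeneric("gammaMatrix"))

#' Model-implied phenotypic covariance for one sex
#' @param object an \code{NTFEquilibrium}.
#' @param sex \code{"m"} or \code{"f"}.
#' @export
setGeneric("phenotypicCov",
           function(object, sex = c("m", "f")) standardGeneric("phenotypicCov"))

#' Number of free parameters of a model or fit
#'
#' Equality-constrained groups count once; equilibrium constraints (such as
#' forcing the q off-diagonal to zero) reduce the count.
#' @param object an \code{NTFModel} or \code{NTFFit}.
#' @export
setGeneric("nFreeParams", function(object) standardGeneric("nFreeParams"))

#' -2 log-likelihood of a fit
#' @param object an \code{NTFFit}.
#' @export
setGeneric("minus2LL", function(object) standardGeneric("minus2LL"))

#' Akaike information criterion of a fit
#'
#' Defined as -2 log-likelihood + 2k with k the free-parameter count; lower
#' is better, and comparisons are valid across non-nested model variants fit
#' to identical data.
#' @param object an \code{NTFFit}.
#' @export
setGeneric("aic", function(object) standardGeneric("aic"))

#' Fitted model with estimates in place
#' @param object an \code{NTFFit}.
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' Equilibrium state at the fitted optimum
#' @param object an \code{NTFFit}.
#' @export
setGeneric("equilibrium", function(object) standardGeneric("equilibrium"))
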