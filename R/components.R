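# Variance components, heritabilities, genetic correlations and
# assortment-inflation summaries.

#' Variance-component report for a model at equilibrium
#'
#' Per sex: the 2x2 (co)variance contributed by each latent source
#' (V_A includes the male-specific B factor and its assortment-induced cross
#' terms for males), narrow- and broad-sense heritabilities, the additive
#' genetic correlation, the inflation of additive genetic (co)variance due
#' to assortative mating (observed a q a' versus the random-mating
#' counterfactual a I a', in percent), and the share of the cross-trait
#' phenotypic covariance attributable to each component.
#'
#' @param model an \code{NTFModel}.
#' @param eq its \code{NTFEquilibrium}.
#' @return a list of class \code{ntfComponents} with elements \code{m} and
#'   \code{f} (each holding \code{V} — named list of 2x2 component matrices
#'   and \code{VP} —, \code{h2Narrow}, \code{h2Broad}, \code{rA},
#'   \code{inflation}, \code{covShares}).
#' @export
varianceComponents <- function(model, eq) {
  stopifnot(is(model, "NTFModel"), is(eq, "NTFEquilibrium"))
  if (!eq@converged) stop("equilibrium has not converged")
  eql <- .eq_list(eq)
  out <- list()
  for (sex in c("m", "f")) {
    L <- .sex_loading(model, sex)
    w <- .w_of(eql, sex)
    a <- .get_mat(model, paste0("a_", sex))
    q <- qMatrix(eq)
    VA <- L %*% eql$Q %*% t(L)
    VD <- tcrossprod(.get_mat(model, paste0("d_", sex)))
    VS <- tcrossprod(.get_mat(model, paste0("s_", sex)))
    VT <- tcrossprod(.get_mat(model, paste0("t_", sex)))
    VE <- tcrossprod(.get_mat(model, paste0("e_", sex)))
    VC <- tcrossprod(.get_mat(model, paste0("c_", sex)))
    VF <- if (sex == "m") eql$fvM else eql$fvF
    VAF <- L %*% w + t(w) %*% t(L)       # A-F covariance contribution
    VP <- if (sex == "m") eql$vpM else eql$vpF
    if (any(diag(VP) <= 0)) stop("zero phenotypic variance")
    V <- list(A = VA, D = VD, S = VS, T = VT, E = VE, C = VC, F = VF,
              AF = VAF, P = VP)
    h2n <- diag(VA) / diag(VP)
    h2b <- diag(VA + VD) / diag(VP)
    rA <- if (all(diag(VA) > 0)) VA[1, 2] / sqrt(VA[1, 1] * VA[2, 2]) else NA
    aqa <- a %*% q %*% t(a)
    aa <- tcrossprod(a)
    infl <- matrix(NA_real_, 2, 2)
    nz <- aa != 0
    infl[nz] <- 100 * (aqa[nz] - aa[nz]) / aa[nz]
    shares <- vapply(V[c("A", "D", "S", "T", "E", "C", "F", "AF")],
                     function(M) M[1, 2], numeric(1))
    covShares <- if (VP[1, 2] != 0) shares / VP[1, 2] else shares * NA
    out[[sex]] <- list(V = V, h2Narrow = h2n, h2Broad = h2b, rA = rA,
                       inflation = infl, covShares = covShares)
  }
  structure(out, class = "ntfComponents", mode = model@mode)
}

#' @export
print.ntfComponents <- function(x, ...) {
  cat("Variance components (trait1, trait2)\n")
  for (sex in c("m", "f")) {
    s <- x[[sex]]
    cat(sprintf("\n  %s:\n", if (sex == "m") "males" else "females"))
    cat(sprintf("    narrow h2 : %.3f  %.3f\n", s$h2Narrow[1], s$h2Narrow[2]))
    cat(sprintf("    broad  h2 : %.3f  %.3f\n", s$h2Broad[1], s$h2Broad[2]))
    cat(sprintf("    r_A       : %.3f\n", s$rA))
    if (is.finite(s$inflation[1, 1]))
      cat(sprintf("    V_A inflation under assortment: %.1f%%  %.1f%% (cross: %.1f%%)\n",
                  s$inflation[1, 1], s$inflation[2, 2],
                  if (is.finite(s$inflation[2, 1])) s$inflation[2, 1] else NA))
  }
  invisible(x)
}

#' Percent inflation of an observed (co)variance over a counterfactual
#'
#' The arithmetic used to express how much larger an additive-genetic
#' (co)variance is than it would have been under random mating:
#' 100 (observed - counterfactual) / counterfactual, e.g. an observed
#' cross-trait covariance of .08 versus a random-mating prediction of .03 is
#' 167 percent higher.
#'
#' @param observed observed value(s).
#' @param counterfactual predicted value(s) under the counterfactual.
#' @return percent inflation (vectorised).
#' @export
inflationPercent <- function(observed, counterfactual) {
  if (any(counterfactual == 0)) stop("counterfactual value of zero")
  100 * (observed - counterfactual) / counterfactual
}
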