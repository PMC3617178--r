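# Stationary (equilibrium) moments under assortative mating.
#
# The additive machinery is solved jointly over the stacked latent vector
# G = (A, B): males express G through L_m = [a_m | b], females through
# L_f = [a_f | 0].  Offspring latents follow G_o = (G_fa + G_mo)/2 + xi with
# Var(xi) = I/2 (infinitesimal-model segregation, unaffected by assortment),
# so at equilibrium QG = I + (Gamma + Gamma')/2 where Gamma = Cov(G_fa, G_mo)
# is induced by the spousal copath matrix mu via the copath tracing rule
# cov(X, Y) = cov(X, P_h) mu cov(P_w, Y).  With vertical transmission (F),
# the fixed point extends jointly over (QG, w, fvar, vp) so that offspring
# moments equal parental-generation moments.

.sex_loading <- function(model, sex) {
  if (sex == "m") cbind(.get_mat(model, "a_m"), .get_mat(model, "b"))
  else            cbind(.get_mat(model, "a_f"), matrix(0, 2, 2))
}

.env_var <- function(model, sex) {
  # non-additive + environmental variance excluding F: d d' + s s' + t t' +
  # e e' + c c'
  v <- matrix(0, 2, 2)
  for (fam in c("d", "s", "t", "e", "c")) {
    M <- .get_mat(model, paste0(fam, "_", sex))
    v <- v + tcrossprod(M)
  }
  v
}

# Internal solver: never throws; returns a list with an ok flag so the
# optimizer can treat inadmissible regions as infinite-cost points.
.solve_eq <- function(model, tol = 1e-10, maxIter = 10000L, damping = 0.5,
                      init = NULL) {
  .solve_eq_mats(.model_mats(model), tol = tol, maxIter = maxIter,
                 damping = damping, init = init)
}

.solve_eq_mats <- function(mats, tol = 1e-10, maxIter = 10000L,
                           damping = 0.5, init = NULL) {
  Lm <- mats$Lm
  Lf <- mats$Lf
  mu <- mats$mu
  hasF <- mats$mode == "ABDFTE"
  vfs <- mats$vF$m; vfd <- mats$vF$f
  vms <- mats$vM$m; vmd <- mats$vM$f
  envM <- mats$envM
  envF <- mats$envF
  I4 <- diag(4)
  tLm <- t(Lm); tLf <- t(Lf); tmu <- t(mu)
  tvfs <- t(vfs); tvfd <- t(vfd); tvms <- t(vms); tvmd <- t(vmd)

  # warm start (used by the optimiser between neighbouring evaluations)
  if (!is.null(init) && all(is.finite(init$Q))) {
    Q <- init$Q; wM <- init$wM; wF <- init$wF
    fvM <- init$fvM; fvF <- init$fvF
  } else {
    Q <- I4
    wM <- wF <- matrix(0, 4, 2)
    fvM <- fvF <- matrix(0, 2, 2)
  }
  Gamma <- matrix(0, 4, 4)
  vpM <- vpF <- diag(2)
  muZero <- all(mu == 0)

  iter <- 0L; resid <- Inf
  repeat {
    iter <- iter + 1L
    CgpM <- Q %*% tLm + wM
    CgpF <- Q %*% tLf + wF
    vpM <- Lm %*% CgpM + crossprod(wM, tLm) + fvM + envM
    vpF <- Lf %*% CgpF + crossprod(wF, tLf) + fvF + envF
    Gamma <- CgpM %*% tcrossprod(mu, CgpF)
    Qn <- I4 + 0.5 * (Gamma + t(Gamma))
    if (hasF) {
      Omega <- vpM %*% mu %*% vpF
      hub <- 0.5 * (CgpM + CgpF %*% tmu %*% vpM)     # Cov(G_o, P_father)
      wife <- 0.5 * (CgpF + CgpM %*% mu %*% vpF)     # Cov(G_o, P_mother)
      wMn <- hub %*% tvfs + wife %*% tvms
      wFn <- hub %*% tvfd + wife %*% tvmd
      fvMn <- vfs %*% vpM %*% tvfs + vms %*% vpF %*% tvms +
              vfs %*% Omega %*% tvms + vms %*% t(Omega) %*% tvfs
      fvFn <- vfd %*% vpM %*% tvfd + vmd %*% vpF %*% tvmd +
              vfd %*% Omega %*% tvmd + vmd %*% t(Omega) %*% tvfd
    } else {
      wMn <- wFn <- matrix(0, 4, 2)
      fvMn <- fvFn <- matrix(0, 2, 2)
    }
    resid <- max(abs(Qn - Q), abs(wMn - wM), abs(wFn - wF),
                 abs(fvMn - fvM), abs(fvFn - fvF))
    Q  <- Q  + damping * (Qn - Q)
    wM <- wM + damping * (wMn - wM)
    wF <- wF + damping * (wFn - wF)
    fvM <- fvM + damping * (fvMn - fvM)
    fvF <- fvF + damping * (fvFn - fvF)
    if (!all(is.finite(Q))) {
      return(list(ok = FALSE, reason = "diverged", nIter = iter,
                  residual = Inf))
    }
    if (resid <= tol || (muZero && !hasF)) break
    if (iter >= maxIter)
      return(list(ok = FALSE, reason = "not converged", nIter = iter,
                  residual = resid))
  }
  # recompute implied phenotypic covariance at the solution
  CgpM <- Q %*% tLm + wM
  CgpF <- Q %*% tLf + wF
  vpM <- Lm %*% CgpM + crossprod(wM, tLm) + fvM + envM
  vpF <- Lf %*% CgpF + crossprod(wF, tLf) + fvF + envF
  Gamma <- CgpM %*% tcrossprod(mu, CgpF)
  Q <- 0.5 * (Q + t(Q))
  psd <- function(M) min(eigen(M, symmetric = TRUE,
                               only.values = TRUE)$values) >= -1e-8
  if (!psd(Q) || !psd(vpM) || !psd(vpF))
    return(list(ok = FALSE, reason = "not positive semi-definite",
                nIter = iter, residual = resid))
  list(ok = TRUE, Q = Q, Gamma = Gamma, wM = wM, wF = wF,
       fvM = fvM, fvF = fvF, vpM = vpM, vpF = vpF,
       nIter = iter, residual = resid)
}

.as_equilibrium <- function(sol) {
  new("NTFEquilibrium", QG = sol$Q, gamma = sol$Gamma,
      wM = sol$wM, wF = sol$wF, fvarM = sol$fvM, fvarF = sol$fvF,
      vpM = sol$vpM, vpF = sol$vpF, converged = TRUE,
      nIter = as.integer(sol$nIter), residual = sol$residual)
}

#' Solve the mating equilibrium of a model
#'
#' Damped fixed-point iteration, starting from the random-mating state
#' (q = I), of the stationarity system implied by the model's generative
#' recursion.  With \code{mu = 0} (random mating or social homogamy) the
#' result is exact: q = I and Gamma = 0.  In the univariate embedding with
#' additive variance a-squared and scalar copath mu, the fixed point equals
#' the smaller root of the quadratic a^2 mu q^2 - q + 1 = 0.
#'
#' @param model an \code{NTFModel}.
#' @param tol max-norm residual tolerance of the fixed point.
#' @param maxIter maximum iterations.
#' @param damping step fraction in (0, 1]; 0.5 is robust for this mildly
#'   nonlinear system.
#' @return an \code{NTFEquilibrium}.
#' @section Errors: non-convergence (assortment too strong or inadmissible
#'   parameters) and loss of positive semi-definiteness of q or the implied
#'   phenotypic covariance raise errors of class \code{ntfInadmissible};
#'   nothing is silently clamped.
#' @examples
#' m <- ntfModel("ABDSTE", drop = c("mu"))
#' qMatrix(solveEquilibrium(m))   # identity under random mating
#' @export
solveEquilibrium <- function(model, tol = 1e-10, maxIter = 10000L,
                             damping = 0.5) {
  stopifnot(is(model, "NTFModel"), tol > 0)
  sol <- .solve_eq(model, tol = tol, maxIter = maxIter, damping = damping)
  if (!sol$ok)
    stop(structure(class = c("ntfInadmissible", "error", "condition"),
                   list(message = paste0("equilibrium solve failed: ",
                                         sol$reason,
                                         sprintf(" (iter %d, residual %.3g)",
                                                 sol$nIter, sol$residual)),
                        call = sys.call(-1))))
  .as_equilibrium(sol)
}

#' @rdname qMatrix
#' @export
setMethod("qMatrix", "NTFEquilibrium", function(object) object@QG[1:2, 1:2])

#' @rdname qBMatrix
#' @export
setMethod("qBMatrix", "NTFEquilibrium", function(object) object@QG[3:4, 3:4])

#' @rdname gammaMatrix
#' @export
setMethod("gammaMatrix", "NTFEquilibrium",
          function(object) object@gamma[1:2, 1:2])

#' @rdname phenotypicCov
#' @export
setMethod("phenotypicCov", "NTFEquilibrium", function(object, sex = c("m", "f")) {
  sex <- match.arg(sex)
  if (sex == "m") object@vpM else object@vpF
})

setMethod("show", "NTFEquilibrium", function(object) {
  cat("NTFEquilibrium (converged in", object@nIter, "iterations, residual",
      format(object@residual, digits = 3), ")\n")
  cat("q (equilibrium additive-genetic covariance):\n")
  print(round(qMatrix(object), 4))
  cat("Gamma (spousal additive-genetic covariance):\n")
  print(round(gammaMatrix(object), 4))
  invisible(object)
})
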