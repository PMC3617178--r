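# Maximum-likelihood estimation and likelihood-ratio machinery.

#' Fit a nuclear twin family model by FIML
#'
#' Minimises the raw-data -2 log-likelihood over the model's free parameters
#' with box constraints (path-matrix diagonals nonnegative, cross-sex
#' correlations in [-1, 1]); the copath matrix is unconstrained within the
#' convergent region, and parameter points where the equilibrium fails to
#' converge or loses positive semi-definiteness are treated as
#' infinite-cost, never clamped.  Multi-start with jittered initial values
#' guards against the mildly multimodal surface.
#'
#' @param model an \code{NTFModel} whose current values seed the first start.
#' @param data a family table.
#' @param nStarts number of starts (first from the model's values, the rest
#'   jittered).
#' @param seed RNG seed for the jitter.
#' @param jitterSD standard deviation of the start jitter in path units.
#' @param control passed to \code{\link[stats]{nlminb}}.
#' @param verbose print per-start progress.
#' @return an \code{\link{NTFFit}}.
#' @export
fitNTF <- function(model, data, nStarts = 5L, seed = 1L, jitterSD = 0.1,
                   control = list(iter.max = 1000L, eval.max = 4000L),
                   verbose = FALSE) {
  stopifnot(is(model, "NTFModel"), nStarts >= 1L)
  prep <- .prepare_families(data)
  if (!length(prep$groups)) stop("no families with observed data")
  theta0 <- .pack_theta(model)
  lower <- attr(theta0, "lower"); upper <- attr(theta0, "upper")
  nEval <- 0L

  # the q off-diagonal constraint restricts the parameter space to points
  # whose ordinary equilibrium has q12 = 0 (enforced by a quadratic
  # penalty, tightened in a second pass); clamping q12 inside the solver
  # instead would leave Gamma free to carry the cross-trait flow and the
  # constraint would cost nothing
  # compiled registry: the objective writes theta straight into a value
  # vector and never touches the registry data.frame
  cmp <- .compile_registry(model)
  reg0 <- model@params
  freeRows <- which(reg0$free)
  groupPos <- match(reg0$group[freeRows], .free_groups(model))
  meanIdx <- list(
    m = match(if (model@meansModel == "trait") c("mean_1", "mean_2")
              else c("mean_m_1", "mean_m_2"), reg0$param),
    f = match(if (model@meansModel == "trait") c("mean_1", "mean_2")
              else c("mean_f_1", "mean_f_2"), reg0$param))
  meansFromVals <- function(vals) {
    if (model@meansModel == "zero")
      list(m = c(0, 0), f = c(0, 0))
    else
      list(m = vals[meanIdx$m], f = vals[meanIdx$f])
  }

  penalty <- 0
  warm <- NULL
  objective <- function(theta) {
    nEval <<- nEval + 1L
    vals <- cmp$values
    vals[freeRows] <- theta[groupPos]
    mats <- .mats_from_values(cmp, vals)
    sol <- .solve_eq_mats(mats, tol = 1e-9, maxIter = 2000L, init = warm)
    if (!sol$ok && !is.null(warm))   # retry cold: keeps the objective a
      sol <- .solve_eq_mats(mats, tol = 1e-9, maxIter = 2000L)  # function of theta
    if (!sol$ok) return(1e10)
    warm <<- sol[c("Q", "wM", "wF", "fvM", "fvF")]
    val <- .negloglik_core(mats, meansFromVals(vals), sol, prep)
    if (!is.finite(val)) return(1e10)
    val + penalty * sol$Q[1, 2]^2
  }

  set.seed(seed)
  starts <- vector("list", nStarts)
  starts[[1]] <- as.numeric(theta0)
  if (nStarts > 1) for (s in 2:nStarts) {
    th <- as.numeric(theta0) + stats::rnorm(length(theta0), 0, jitterSD)
    starts[[s]] <- pmin(pmax(th, lower + 1e-6), upper - 1e-6)
  }
  # an infeasible start (e.g. estimates inherited from a larger model that
  # land outside the convergent assortment region after an edit) is blended
  # toward the registry defaults until the equilibrium is solvable
  reg <- model@params
  gidx <- match(.free_groups(model), reg$group)
  defaults <- mapply(function(m, i, j) .default_value(m, i, j),
                     reg$mat[gidx], reg$i[gidx], reg$j[gidx])
  defaults[reg$mat[gidx] == "rcor"] <- 0.9
  defaults[reg$mat[gidx] == "mean"] <- 0
  starts <- lapply(starts, function(st) {
    if (objective(st) < 1e9) return(st)
    for (lam in c(0.5, 0.75, 0.9, 1)) {
      cand <- (1 - lam) * st + lam * defaults
      if (objective(cand) < 1e9) return(cand)
    }
    st
  })

  best <- NULL; bestVal <- Inf; bestIdx <- 0L
  if (model@constrainQ) penalty <- 1e6
  diag_rows <- vector("list", nStarts)
  for (s in seq_len(nStarts)) {
    res <- tryCatch(
      stats::nlminb(starts[[s]], objective, lower = lower, upper = upper,
                    control = control),
      error = function(e) NULL)
    ok <- !is.null(res) && is.finite(res$objective) && res$objective < 1e9
    diag_rows[[s]] <- data.frame(
      start = s,
      objective = if (is.null(res)) NA_real_ else res$objective,
      convergence = if (is.null(res)) NA_integer_ else res$convergence,
      ok = ok)
    if (verbose)
      message(sprintf("start %d: -2lnL = %s", s,
                      if (ok) format(res$objective, digits = 10) else "failed"))
    if (ok && res$objective < bestVal) {
      best <- res; bestVal <- res$objective; bestIdx <- s
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  if (is.null(best))
    stop(structure(class = c("ntfFitFailure", "error", "condition"),
                   list(message = "all starts failed to converge",
                        call = sys.call(-1), diagnostics = diagnostics)))

  if (model@constrainQ) {
    # tighten the equilibrium constraint from the first-pass solution,
    # unless the first pass already holds it to numerical precision
    sol1 <- .solve_eq(.unpack_theta(model, best$par), tol = 1e-10,
                      maxIter = 10000L)
    if (!sol1$ok || abs(sol1$Q[1, 2]) > 2e-4) {
      penalty <- 1e8
      res2 <- tryCatch(
        stats::nlminb(best$par, objective, lower = lower, upper = upper,
                      control = control),
        error = function(e) NULL)
      if (!is.null(res2) && is.finite(res2$objective) && res2$objective < 1e9)
        best <- res2
    }
  }

  fitted <- .unpack_theta(model, best$par)
  eqSol <- .solve_eq(fitted, tol = 1e-12, maxIter = 20000L)
  if (!eqSol$ok) stop("equilibrium inadmissible at the reported optimum")
  m2ll <- .negloglik_prepared(fitted, eqSol, prep)
  new("NTFFit", model = fitted, equilibrium = .as_equilibrium(eqSol),
      minus2LL = m2ll, k = nFreeParams(fitted),
      converged = best$convergence == 0L,
      nEvaluations = nEval, bestStart = bestIdx,
      startDiagnostics = diagnostics)
}

#' Upper-tail chi-square probability
#'
#' Convenience wrapper over \code{\link[stats]{pchisq}} used for every
#' likelihood-ratio test the model-selection ladder prints.
#'
#' @param x statistic, nonnegative.
#' @param df degrees of freedom, positive integer.
#' @export
chiSqTail <- function(x, df) {
  if (any(x < 0)) stop("negative chi-square statistic")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood-ratio test of a reduced model against the full model
#'
#' @param full,reduced \code{NTFFit}s of nested models on identical data
#'   (\code{reduced} must have fewer free parameters).
#' @param threshold retention threshold: the tested parameters are retained
#'   when p < threshold (the study convention is a liberal .10).
#' @return an \code{\link{NTFTest}}.
#' @export
lrTest <- function(full, reduced, threshold = 0.10) {
  stopifnot(is(full, "NTFFit"), is(reduced, "NTFFit"))
  df <- full@k - reduced@k
  if (df < 1) stop("models are not nested (reduced must have fewer parameters)")
  chi2 <- reduced@minus2LL - full@minus2LL
  clamped <- FALSE
  if (chi2 < 0) {
    # numerical-noise clamp, scaled to the optimizer's relative precision
    if (chi2 > -max(1e-6, 1e-8 * abs(full@minus2LL))) {
      chi2 <- 0; clamped <- TRUE
    }
    else stop("reduced model fits better than full by ",
              format(-chi2, digits = 6),
              "; the full model appears unconverged")
  }
  p <- chiSqTail(chi2, df)
  new("NTFTest", chi2 = chi2, df = as.integer(df), p = p,
      retained = p < threshold, clamped = clamped)
}

# ---- accessors / methods -----------------------------------------------

#' @rdname minus2LL
#' @export
setMethod("minus2LL", "NTFFit", function(object) object@minus2LL)

#' @rdname aic
#' @export
setMethod("aic", "NTFFit",
          function(object) object@minus2LL + 2 * object@k)

#' @rdname nFreeParams
#' @export
setMethod("nFreeParams", "NTFFit", function(object) object@k)

#' @rdname estimates
#' @export
setMethod("estimates", "NTFFit", function(object) object@model)

#' @rdname equilibrium
#' @export
setMethod("equilibrium", "NTFFit", function(object) object@equilibrium)

setMethod("show", "NTFFit", function(object) {
  cat(sprintf("NTFFit: %s model, -2lnL = %.3f, k = %d, AIC = %.3f\n",
              object@model@mode, object@minus2LL, object@k, aic(object)))
  cat(sprintf("  converged: %s (best of %d start(s), %d evaluations)\n",
              object@converged, nrow(object@startDiagnostics),
              object@nEvaluations))
  invisible(object)
})

setMethod("show", "NTFTest", function(object) {
  cat(sprintf("chi2(%d) = %.4g, p = %.4g -> %s%s\n", object@df, object@chi2,
              object@p,
              if (object@retained) "parameters retained"
              else "reduction accepted",
              if (object@clamped) " [negative statistic clamped to 0]" else ""))
  invisible(object)
})

#' Write a fit or test as a structured text report
#'
#' @param object an \code{NTFFit} or \code{NTFTest}.
#' @param path output file.
#' @export
writeReport <- function(object, path) {
  lines <- if (is(object, "NTFFit")) {
    reg <- object@model@params
    c(sprintf("mode: %s", object@model@mode),
      sprintf("minus2LL: %.10g", object@minus2LL),
      sprintf("k: %d", object@k),
      sprintf("aic: %.10g", aic(object)),
      sprintf("converged: %s", object@converged),
      "estimates:",
      sprintf("  %s: %.8g", reg$param[reg$free], reg$value[reg$free]))
  } else if (is(object, "NTFTest")) {
    c(sprintf("chi2: %.8g", object@chi2),
      sprintf("df: %d", object@df),
      sprintf("p: %.8g", object@p),
      sprintf("retained: %s", object@retained))
  } else stop("unsupported object")
  writeLines(lines, path)
  invisible(path)
}
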