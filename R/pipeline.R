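# End-to-end analysis sequence: phenotype adjustment, three-way
# mating-model comparison, sequential reduction, headline decomposition.

#' Regression-based phenotype adjustment
#'
#' Per trait: least-squares adjustment for sex, age and age squared
#' (optionally within sample), removal (set to missing) of scores more than
#' \code{outlierSD} standard deviations from the mean, and standardization
#' of the residuals to overall mean 0 and variance 1.  Variances within sex
#' are left free.  With a degenerate design (constant age and a single sex)
#' the adjustment falls back to mean-centering with a warning.
#'
#' @param raw a family table on raw scales.
#' @param bySample adjust within each sample label separately.
#' @param outlierSD removal threshold in residual standard deviations.
#' @return list with \code{data} (adjusted family table) and \code{log}
#'   (data.frame of removal counts by trait and sign, plus fitted
#'   coefficients).
#' @export
adjustPhenotypes <- function(raw, bySample = FALSE, outlierSD = 4) {
  raw <- validateFamilyTable(raw)
  logRows <- list(); coefs <- list()
  for (tr in c("trait1", "trait2")) {
    y <- raw[[tr]]
    grp <- if (bySample) raw$sample else rep("all", nrow(raw))
    resid <- rep(NA_real_, length(y))
    for (g in unique(grp)) {
      sel <- grp == g & !is.na(y) & !is.na(raw$age) & !is.na(raw$sex)
      if (!sum(sel)) next
      df <- data.frame(y = y[sel], sex = raw$sex[sel], age = raw$age[sel])
      degenerate <- length(unique(df$sex)) < 2 && stats::var(df$age) == 0
      fit <- if (degenerate) {
        warning("degenerate design (constant age, single sex): ",
                "falling back to mean-centering")
        stats::lm(y ~ 1, data = df)
      } else if (length(unique(df$sex)) < 2) {
        stats::lm(y ~ age + I(age^2), data = df)
      } else if (stats::var(df$age) == 0) {
        stats::lm(y ~ sex, data = df)
      } else {
        stats::lm(y ~ sex + age + I(age^2), data = df)
      }
      resid[sel] <- stats::residuals(fit)
      coefs[[paste(tr, g, sep = ".")]] <- stats::coef(fit)
    }
    s <- stats::sd(resid, na.rm = TRUE)
    m <- mean(resid, na.rm = TRUE)
    neg <- which(resid < m - outlierSD * s)
    pos <- which(resid > m + outlierSD * s)
    if (length(neg) + length(pos) > 0) {
      y2 <- y; y2[c(neg, pos)] <- NA
      # refit without the outliers
      resid <- rep(NA_real_, length(y))
      for (g in unique(grp)) {
        sel <- grp == g & !is.na(y2) & !is.na(raw$age) & !is.na(raw$sex)
        if (!sum(sel)) next
        df <- data.frame(y = y2[sel], sex = raw$sex[sel], age = raw$age[sel])
        fit <- if (length(unique(df$sex)) < 2 && stats::var(df$age) == 0)
          stats::lm(y ~ 1, data = df)
        else if (length(unique(df$sex)) < 2)
          stats::lm(y ~ age + I(age^2), data = df)
        else if (stats::var(df$age) == 0) stats::lm(y ~ sex, data = df)
        else stats::lm(y ~ sex + age + I(age^2), data = df)
        resid[sel] <- stats::residuals(fit)
        coefs[[paste(tr, g, sep = ".")]] <- stats::coef(fit)
      }
    }
    std <- as.numeric(scale(resid))
    raw[[tr]] <- std
    logRows[[tr]] <- data.frame(trait = tr, negRemoved = length(neg),
                                posRemoved = length(pos),
                                stringsAsFactors = FALSE)
  }
  list(data = raw, log = do.call(rbind, logRows), coefficients = coefs)
}

.default_variants <- function(sexEqual = FALSE, meansModel = "zero") {
  list(
    ABDSTE = ntfModel("ABDSTE", sexEqual = sexEqual, meansModel = meansModel),
    ABDFTE = ntfModel("ABDFTE", sexEqual = sexEqual, meansModel = meansModel),
    ABDCTE = ntfModel("ABDCTE", sexEqual = sexEqual, meansModel = meansModel))
}

#' Compare the three mating-model families by AIC
#'
#' Fits the full ABDSTE and ABDFTE primary-phenotypic-assortment models and
#' the ABDCTE social-homogamy model to the same adjusted data and ranks
#' them by AIC (they are non-nested, so likelihood-ratio tests do not
#' apply).
#'
#' @param data adjusted family table.
#' @param variants named list of three \code{NTFModel}s to use instead of
#'   the full defaults (e.g. sex-equated versions for reduced-scale
#'   studies).
#' @param nStarts,seed,control passed to \code{\link{fitNTF}}.
#' @return list with \code{fits} (named), \code{aic} (named, sorted),
#'   \code{best} (name of the AIC-best variant).
#' @export
compareMatingModels <- function(data, variants = .default_variants(),
                                nStarts = 3L, seed = 1L,
                                control = list(iter.max = 1000L,
                                               eval.max = 4000L)) {
  fits <- list()
  for (nm in names(variants))
    fits[[nm]] <- fitNTF(variants[[nm]], data, nStarts = nStarts,
                         seed = seed, control = control)
  aics <- sort(vapply(fits, aic, numeric(1)))
  list(fits = fits, aic = aics, best = names(aics)[1])
}

# candidate edits for the reduction ladder, as (label, edit-function) pairs
.reduction_candidates <- function(model) {
  mats <- unique(model@params$mat)
  has <- function(m) m %in% mats && any(model@params$free[model@params$mat == m])
  out <- list()
  addDrop <- function(label, d)
    out[[length(out) + 1L]] <<- list(label = label, kind = "drop", what = d)
  addFix <- function(label, nm)
    out[[length(out) + 1L]] <<- list(label = label, kind = "fix", what = nm)
  if (has("t_m") || has("t_f")) addDrop("drop T", "t")
  if (has("b")) addDrop("drop B", "b")
  if (has("r_S")) addFix("fix r_S = 1", "r_S")
  if (has("r_D")) addFix("fix r_D = 1", "r_D")
  if (has("r_T")) addFix("fix r_T = 1", "r_T")
  if (has("d_m") || has("d_f")) addDrop("drop D", "d")
  if (has("s_m") || has("s_f")) addDrop("drop S", "s")
  if (has("v_fs")) addDrop("drop F", "v")
  if (has("c_m") || has("c_f")) addDrop("drop C", "c")
  if (has("mu")) {
    free <- model@params$free & model@params$mat == "mu"
    grp <- model@params$group[free]
    if (all(c("mu_12", "mu_21") %in% model@params$param[free]) &&
        length(unique(grp[model@params$param[free] %in%
                            c("mu_12", "mu_21")])) > 1)
      out[[length(out) + 1L]] <- list(label = "equate mu_12 = mu_21",
                                      kind = "equate",
                                      what = c("mu_12", "mu_21"))
    addDrop("drop mu", "mu")
  }
  out
}

# summed share of both traits' phenotypic variance attributable to a
# matrix family, used to order drop candidates (smallest first)
.variance_share <- function(fit, what) {
  comp <- varianceComponents(fit@model, fit@equilibrium)
  key <- switch(what, t = "T", b = NA, d = "D", s = "S", c = "C",
                v = "F", mu = NA, NA)
  tot <- 0
  for (sex in c("m", "f")) {
    VP <- comp[[sex]]$V$P
    M <- if (what == "b") {
      L <- .sex_loading(fit@model, sex)
      if (sex == "f") matrix(0, 2, 2)
      else comp[[sex]]$V$A - {
        a <- .get_mat(fit@model, "a_m")
        a %*% qMatrix(fit@equilibrium) %*% t(a)
      }
    } else if (!is.na(key)) comp[[sex]]$V[[key]] else matrix(0, 2, 2)
    tot <- tot + sum(diag(M) / diag(VP))
  }
  tot
}

#' Sequential parameter reduction by likelihood-ratio testing
#'
#' Starting from a fitted model, tests candidate structural edits —
#' whole-matrix drops ordered by the share of phenotypic variance they
#' explain (smallest first), cross-sex correlation fixes to 1, the copath
#' symmetry constraint, and finally dropping the copath matrix — each by a
#' chi-square test on -2 log-likelihoods against the current model.  An
#' edit is accepted when p > threshold (the fit changes little); accepted
#' edits accumulate, and the process stops when no candidate remains.
#'
#' @param fit the winning full-model \code{NTFFit}.
#' @param data the adjusted family table the fit used.
#' @param threshold retention threshold (default .10: a liberal criterion,
#'   so a matrix is only dropped when there is little evidence for it in
#'   either trait).
#' @param nStarts,seed,control passed to refits (each refit starts at the
#'   current estimates, so 1 extra jittered start is usually enough).
#' @return list of class \code{ntfSelection}: \code{steps} (data.frame
#'   log), \code{finalFit}.
#' @export
sequentialReduction <- function(fit, data, threshold = 0.10, nStarts = 1L,
                                seed = 1L,
                                control = list(iter.max = 1000L,
                                               eval.max = 4000L)) {
  stopifnot(is(fit, "NTFFit"))
  current <- fit
  steps <- list()
  repeat {
    cands <- .reduction_candidates(current@model)
    if (!length(cands)) break
    # order drop candidates by current variance share, smallest first;
    # fixes/equates keep their ladder position relative to the drops
    shares <- vapply(cands, function(cd)
      if (cd$kind == "drop" && cd$what != "mu")
        .variance_share(current, cd$what) else NA_real_, numeric(1))
    ord <- order(ifelse(is.na(shares), seq_along(cands) * 1e-6 + 1e3,
                        shares))
    accepted <- FALSE
    for (ci in ord) {
      cd <- cands[[ci]]
      red <- switch(cd$kind,
        drop = reduceModel(current@model, drop = cd$what),
        fix = reduceModel(current@model,
                          fix = stats::setNames(list(1), cd$what)),
        equate = reduceModel(current@model, equate = list(cd$what)))
      redFit <- tryCatch(
        fitNTF(red, data, nStarts = nStarts, seed = seed, control = control),
        error = function(e)
          stop("fit failed at reduction step '", cd$label, "': ",
               conditionMessage(e)))
      tst <- lrTest(current, redFit, threshold)
      steps[[length(steps) + 1L]] <- data.frame(
        step = length(steps) + 1L, edit = cd$label, chi2 = tst@chi2,
        df = tst@df, p = tst@p, aic = aic(redFit),
        decision = if (tst@retained) "retained" else "dropped",
        stringsAsFactors = FALSE)
      if (!tst@retained) {
        current <- redFit
        accepted <- TRUE
        break   # re-derive candidates from the reduced model
      }
    }
    if (!accepted) break
  }
  structure(list(steps = do.call(rbind, steps), finalFit = current),
            class = "ntfSelection")
}

#' @export
print.ntfSelection <- function(x, ...) {
  cat("Sequential reduction log:\n")
  print(x$steps, row.names = FALSE, digits = 4)
  cat("\nFinal model:\n")
  show(x$finalFit)
  invisible(x)
}

#' Decompose the cross-trait genetic correlation of a final model
#'
#' Reports per-sex narrow and broad heritabilities and the additive genetic
#' correlation r_A, then tests its sources by nested refits: the pleiotropy
#' test zeroes the off-diagonal Cholesky paths of a_m and a_f (df = 2); the
#' gametic-phase-disequilibrium test restricts the fit to parameter points
#' whose equilibrium q matrix has a zero off-diagonal (df = 1); the joint
#' test (r_A = 0) applies both (df = 3).  Also reports
#' how much higher the additive genetic (co)variances are than they would
#' be under random mating (q = I counterfactual), in percent.
#'
#' @param fit the final \code{NTFFit}.
#' @param data the adjusted family table.
#' @param nStarts,seed,control passed to the constrained refits.
#' @return list of class \code{ntfDecomposition}.
#' @export
decomposeFinal <- function(fit, data, nStarts = 1L, seed = 1L,
                           control = list(iter.max = 1000L,
                                          eval.max = 4000L)) {
  stopifnot(is(fit, "NTFFit"))
  comp <- varianceComponents(fit@model, fit@equilibrium)
  refit <- function(model) fitNTF(model, data, nStarts = nStarts,
                                  seed = seed, control = control)
  offA <- list(a_m_21 = 0, a_f_21 = 0)
  free <- fit@model@params$param[fit@model@params$free]
  offA <- offA[names(offA) %in% free]
  tests <- list()
  if (length(offA) >= 1) {
    pleio <- refit(reduceModel(fit@model, fix = offA))
    tests$pleiotropy <- lrTest(fit, pleio)
  }
  if (fit@model@mode != "ABDCTE" && !fit@model@constrainQ) {
    gpd <- refit(reduceModel(fit@model, constrainQ = TRUE))
    tests$gpd <- lrTest(fit, gpd)
    if (length(offA) >= 1) {
      both <- refit(reduceModel(fit@model, fix = offA, constrainQ = TRUE))
      tests$rA_zero <- lrTest(fit, both)
    }
  }
  # assortment inflation: observed a q a' versus the q = I counterfactual
  inflation <- list(m = comp$m$inflation, f = comp$f$inflation)
  structure(list(components = comp, tests = tests, inflation = inflation),
            class = "ntfDecomposition")
}

#' @export
print.ntfDecomposition <- function(x, ...) {
  print(x$components)
  cat("\nSource tests:\n")
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %-11s chi2(%d) = %.3f, p = %.4g\n", nm, t@df, t@chi2,
                t@p))
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Adjust phenotypes, compare the three mating-model families by AIC,
#' sequentially reduce the winner, and decompose the final model's genetic
#' correlation.  With an output directory, writes the step log and all fit
#' reports as structured text.
#'
#' @param data a raw family table (or a path readable by
#'   \code{\link{readFamilyTable}}).
#' @param seed seed controlling all fitting randomness (recorded in the
#'   report).
#' @param threshold reduction threshold.
#' @param variants passed to \code{\link{compareMatingModels}}.
#' @param nStarts starts for the three full fits.
#' @param out optional output directory for text reports.
#' @param adjust set \code{FALSE} if \code{data} is already adjusted.
#' @return list of class \code{ntfPipelineReport}: \code{adjustmentLog},
#'   \code{comparison}, \code{selection}, \code{decomposition},
#'   \code{seed}.
#' @export
runPipeline <- function(data, seed = 1L, threshold = 0.10,
                        variants = .default_variants(), nStarts = 3L,
                        out = NULL, adjust = TRUE) {
  if (is.character(data)) data <- readFamilyTable(data)
  adjLog <- NULL
  if (adjust) {
    adj <- adjustPhenotypes(data)
    data <- adj$data; adjLog <- adj$log
  }
  cmp <- compareMatingModels(data, variants = variants, nStarts = nStarts,
                             seed = seed)
  sel <- sequentialReduction(cmp$fits[[cmp$best]], data,
                             threshold = threshold, seed = seed)
  dec <- decomposeFinal(sel$finalFit, data, seed = seed)
  rep <- structure(list(adjustmentLog = adjLog, comparison = cmp,
                        selection = sel, decomposition = dec, seed = seed),
                   class = "ntfPipelineReport")
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(sel$steps, file.path(out, "selection_steps.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (nm in names(cmp$fits))
      writeReport(cmp$fits[[nm]], file.path(out, paste0("fit_", nm, ".txt")))
    writeReport(sel$finalFit, file.path(out, "fit_final.txt"))
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("winning mode: %s", cmp$best),
                 sprintf("final -2lnL: %.6f", minus2LL(sel$finalFit)),
                 sprintf("final AIC: %.6f", aic(sel$finalFit))),
               file.path(out, "summary.txt"))
  }
  rep
}

#' @export
print.ntfPipelineReport <- function(x, ...) {
  cat("AIC comparison:\n"); print(round(x$comparison$aic, 2))
  cat("\n"); print(x$selection)
  cat("\n"); print(x$decomposition)
  invisible(x)
}
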