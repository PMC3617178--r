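# Moment-check harness: empirical versus analytic moments with
# Monte-Carlo standard errors.

# extract paired trait matrices for two roles within families (vectorised)
.role_pairs <- function(fam, r1, r2) {
  a <- fam[fam$role == r1, ]; b <- fam[fam$role == r2, ]
  m <- match(a$family_id, b$family_id)
  keep <- !is.na(m)
  list(x = as.matrix(a[keep, c("trait1", "trait2")]),
       y = as.matrix(b[m[keep], c("trait1", "trait2")]),
       sex1 = a$sex[keep], sex2 = b$sex[m[keep]],
       zyg = a$zygosity[keep])
}

# MC standard error of a cross-covariance element under joint normality
.cov_se <- function(Sxx, Syy, Sxy, n) sqrt((Sxx * Syy + Sxy^2) / (n - 1))

.check_block <- function(x, y, analytic, label, minN) {
  n <- nrow(x)
  if (n < minN) return(NULL)
  Sx <- stats::cov(x); Sy <- stats::cov(y)
  Exy <- crossprod(sweep(x, 2, colMeans(x)), sweep(y, 2, colMeans(y))) /
    (n - 1)
  rows <- list()
  for (i in 1:2) for (j in 1:2) {
    se <- .cov_se(Sx[i, i], Sy[j, j], Exy[i, j], n)
    z <- (Exy[i, j] - analytic[i, j]) / se
    rows[[length(rows) + 1L]] <- data.frame(
      block = label, element = sprintf("%d%d", i, j), n = n,
      empirical = Exy[i, j], analytic = analytic[i, j], se = se, z = z,
      pass = abs(z) <= 4, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare empirical family moments against the analytic model
#'
#' Tabulates, for every relative-pair block available in a simulated family
#' table (self, spouse, MZ and DZ twins by sex, twin-sib and sib-sib pairs,
#' parent-offspring), the empirical cross-covariance against the
#' model-implied \code{\link{pairCovariance}} block, with Monte-Carlo
#' standard errors; a block passes when every element is within 4 SE.
#'
#' @param fam a family table on the standardized scale (from
#'   \code{\link{simulateFamilies}}).
#' @param model the generating \code{NTFModel}.
#' @param eq its \code{NTFEquilibrium} (solved if omitted).
#' @param minN minimum pairs per block for a comparison to be attempted.
#' @return data.frame with one row per block element, including z-scores
#'   and pass flags.
#' @export
momentCheck <- function(fam, model, eq = NULL, minN = 500L) {
  if (is.null(eq)) eq <- solveEquilibrium(model)
  res <- list()
  add <- function(d) if (!is.null(d)) res[[length(res) + 1L]] <<- d

  # self blocks per sex
  for (sx in c("m", "f")) {
    sel <- fam$sex == sx & !is.na(fam$trait1)
    X <- as.matrix(fam[sel, c("trait1", "trait2")])
    if (nrow(X) >= minN) {
      an <- pairCovariance(model, eq, "self", sx, sx)
      add(.check_block(X, X, an, paste0("self_", sx), minN))
    }
  }
  # spouse
  pr <- .role_pairs(fam, "father", "mother")
  add(.check_block(pr$x, pr$y, pairCovariance(model, eq, "spouse", "m", "f"),
                   "spouse", minN))
  # twin pairs by zygosity and sex combination
  pr <- .role_pairs(fam, "twin1", "twin2")
  for (zg in c("MZ", "DZ")) {
    for (ss in list(c("m", "m"), c("f", "f"), c("m", "f"))) {
      sel <- pr$zyg == zg & pr$sex1 == ss[1] & pr$sex2 == ss[2]
      if (!sum(sel)) next
      rel <- if (zg == "MZ") "MZ" else "DZ"
      an <- pairCovariance(model, eq, rel, ss[1], ss[2])
      add(.check_block(pr$x[sel, , drop = FALSE], pr$y[sel, , drop = FALSE],
                       an, paste(zg, ss[1], ss[2], sep = "_"), minN))
    }
  }
  # twin-sib and sib-sib
  for (rp in list(c("twin1", "sib1"), c("sib1", "sib2"))) {
    pr <- .role_pairs(fam, rp[1], rp[2])
    if (!nrow(pr$x)) next
    for (ss in list(c("m", "m"), c("f", "f"), c("m", "f"), c("f", "m"))) {
      sel <- pr$sex1 == ss[1] & pr$sex2 == ss[2]
      if (!sum(sel)) next
      an <- pairCovariance(model, eq, "sib", ss[1], ss[2])
      add(.check_block(pr$x[sel, , drop = FALSE], pr$y[sel, , drop = FALSE],
                       an, paste(rp[1], rp[2], ss[1], ss[2], sep = "_"),
                       minN))
    }
  }
  # parent-offspring (offspring rows first)
  for (par in c("father", "mother")) {
    for (off in c("twin1", "sib1")) {
      pr <- .role_pairs(fam, off, par)
      if (!nrow(pr$x)) next
      ps <- if (par == "father") "m" else "f"
      for (os in c("m", "f")) {
        sel <- pr$sex1 == os
        if (!sum(sel)) next
        an <- pairCovariance(model, eq, "parent_offspring", os, ps)
        add(.check_block(pr$x[sel, , drop = FALSE], pr$y[sel, , drop = FALSE],
                         an, paste(off, par, os, sep = "_"), minN))
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("insufficient sample for requested tolerance")
  rownames(out) <- NULL
  out
}
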