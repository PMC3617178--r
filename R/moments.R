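# Model-implied covariance blocks between relatives, and whole-family
# mean vectors / covariance matrices.

# One-shot extraction of every parameter matrix a model needs; the fitting
# hot path calls this once per parameter vector instead of re-indexing the
# registry for every block.
# Precompiled index map from the registry into a plain value vector, so
# the fitting hot path never touches the data.frame.
.compile_registry <- function(model) {
  reg <- model@params
  mats <- c("a_m", "a_f", "b", "d_m", "d_f", "s_m", "s_f", "t_m", "t_f",
            "e_m", "e_f", "c_m", "c_f", "mu", "v_fs", "v_fd", "v_ms",
            "v_md")
  idx <- lapply(mats, function(nm) {
    rows <- which(reg$mat == nm)
    list(rows = rows, pos = cbind(reg$i[rows], reg$j[rows]))
  })
  names(idx) <- mats
  list(mode = model@mode, values = reg$value, idx = idx,
       rcor = vapply(c("r_D", "r_S", "r_T"), function(nm) {
         k <- match(nm, reg$param); if (is.na(k)) NA_integer_ else k
       }, integer(1)))
}

# Parameter matrices (with precomputed transposes and cross products) from
# a compiled registry and a value vector.
.mats_from_values <- function(cmp, vals) {
  g <- function(nm) {
    M <- matrix(0, 2, 2)
    ix <- cmp$idx[[nm]]
    if (length(ix$rows)) M[ix$pos] <- vals[ix$rows]
    M
  }
  rc <- function(k) if (is.na(cmp$rcor[k])) 1 else vals[cmp$rcor[k]]
  xp <- function(M) list(m = list(m = tcrossprod(M$m),
                                  f = tcrossprod(M$m, M$f)),
                         f = list(m = tcrossprod(M$f, M$m),
                                  f = tcrossprod(M$f)))
  d <- list(m = g("d_m"), f = g("d_f"))
  s <- list(m = g("s_m"), f = g("s_f"))
  tt <- list(m = g("t_m"), f = g("t_f"))
  cc <- list(m = g("c_m"), f = g("c_f"))
  e <- list(m = g("e_m"), f = g("e_f"))
  dd <- xp(d); ss <- xp(s); ttp <- xp(tt); ccp <- xp(cc)
  Lm <- cbind(g("a_m"), g("b"))
  Lf <- cbind(g("a_f"), matrix(0, 2, 2))
  list(
    mode = cmp$mode,
    Lm = Lm, Lf = Lf, tLm = t(Lm), tLf = t(Lf),
    mu = if (cmp$mode == "ABDCTE") matrix(0, 2, 2) else g("mu"),
    d = d, s = s, t = tt, e = e, c = cc,
    dd = dd, ss = ss, ttp = ttp, ccp = ccp,
    envM = dd$m$m + ss$m$m + ttp$m$m + ccp$m$m + tcrossprod(e$m),
    envF = dd$f$f + ss$f$f + ttp$f$f + ccp$f$f + tcrossprod(e$f),
    vF = list(m = g("v_fs"), f = g("v_fd")),
    vM = list(m = g("v_ms"), f = g("v_md")),
    rD = rc(1), rS = rc(2), rT = rc(3))
}

.model_mats <- function(model) {
  cmp <- .compile_registry(model)
  .mats_from_values(cmp, cmp$values)
}

# plain-list view of an equilibrium, used on hot paths to avoid repeated
# S4 slot dispatch; fields mirror the NTFEquilibrium slots
.eq_list <- function(eq) {
  if (is.list(eq)) return(eq)
  list(Q = eq@QG, Gamma = eq@gamma, wM = eq@wM, wF = eq@wF,
       fvM = eq@fvarM, fvF = eq@fvarF, vpM = eq@vpM, vpF = eq@vpF)
}

# F covariance between two offspring of the same parents with sexes s1, s2
.f_cov_mats <- function(mats, eq, s1, s2) {
  if (mats$mode != "ABDFTE") return(matrix(0, 2, 2))
  Omega <- eq$vpM %*% mats$mu %*% eq$vpF
  vF1 <- mats$vF[[s1]]; vM1 <- mats$vM[[s1]]
  vF2 <- mats$vF[[s2]]; vM2 <- mats$vM[[s2]]
  vF1 %*% eq$vpM %*% t(vF2) + vM1 %*% eq$vpF %*% t(vM2) +
    vF1 %*% Omega %*% t(vM2) + vM1 %*% t(Omega) %*% t(vF2)
}

.w_of <- function(eq, sex) if (sex == "m") eq$wM else eq$wF

# the algebra behind pairCovariance, on a cached matrix set and a
# plain-list equilibrium
.pair_cov_mats <- function(mats, eq, relationship, s1, s2) {
  L1 <- if (s1 == "m") mats$Lm else mats$Lf
  tL2 <- if (s2 == "m") mats$tLm else mats$tLf
  hasF <- mats$mode == "ABDFTE"
  Q <- eq$Q
  os <- s1 != s2

  switch(relationship,
    self = {
      if (s1 == "m") eq$vpM else eq$vpF
    },
    spouse = {
      eq$vpM %*% mats$mu %*% eq$vpF + mats$ccp$m$f
    },
    MZ = {
      out <- L1 %*% Q %*% tL2 +
        mats$dd[[s1]][[s1]] + mats$ss[[s1]][[s1]] +
        mats$ttp[[s1]][[s1]] + mats$ccp[[s1]][[s1]]
      if (hasF) {
        w <- .w_of(eq, s1)
        out <- out + L1 %*% w + crossprod(w, tL2) +
          .f_cov_mats(mats, eq, s1, s1)
      }
      out
    },
    DZ = ,
    sib = {
      G <- eq$Gamma
      Ksib <- 0.5 * Q + 0.25 * (G + t(G))
      rD <- if (os) mats$rD else 1
      rS <- if (os) mats$rS else 1
      rT <- if (os) mats$rT else 1
      shT <- if (relationship == "DZ") rT else 0
      out <- L1 %*% Ksib %*% tL2 +
        0.25 * rD * mats$dd[[s1]][[s2]] +
        rS * mats$ss[[s1]][[s2]] +
        shT * mats$ttp[[s1]][[s2]] +
        mats$ccp[[s1]][[s2]]
      if (hasF)
        out <- out + L1 %*% .w_of(eq, s2) + crossprod(.w_of(eq, s1), tL2) +
          .f_cov_mats(mats, eq, s1, s2)
      out
    },
    parent_offspring = {
      # individual 1 is the offspring, individual 2 the parent; the
      # assortment-mediated route runs through the co-parent's full
      # phenotype via the copath rule
      mu <- mats$mu
      CgpM <- Q %*% mats$tLm; CgpF <- Q %*% mats$tLf
      if (hasF) { CgpM <- CgpM + eq$wM; CgpF <- CgpF + eq$wF }
      out <- if (s2 == "m") {
        L1 %*% (0.5 * (CgpM + CgpF %*% crossprod(mu, eq$vpM))) +
          mats$ccp[[s1]]$m
      } else {
        L1 %*% (0.5 * (CgpF + CgpM %*% mu %*% eq$vpF)) +
          mats$ccp[[s1]]$f
      }
      if (hasF) {
        Omega <- eq$vpM %*% mu %*% eq$vpF
        vF <- mats$vF[[s1]]; vM <- mats$vM[[s1]]
        out <- out + if (s2 == "m") vF %*% eq$vpM + vM %*% t(Omega)
                     else vM %*% eq$vpF + vF %*% Omega
      }
      out
    })
}

#' Model-implied covariance between two relatives' trait vectors
#'
#' Returns the 2x2 cross-covariance block between individual 1's and
#' individual 2's (trait1, trait2) implied by the model at its mating
#' equilibrium.  Rows index individual 1.  All blocks equal the stationary
#' cross-moments of the generative recursion that the forward simulator
#' implements, which is the package's brute-force oracle for them.
#'
#' Relationships: \code{"self"} (the phenotypic covariance), \code{"spouse"}
#' (sex1 is the husband), \code{"MZ"}, \code{"DZ"} (DZ co-twins, sharing the
#' twin environment), \code{"sib"} (full siblings not sharing the twin
#' environment: sib-sib or twin-sib pairs), and \code{"parent_offspring"}
#' (sex1 is the offspring, sex2 the parent).
#'
#' @param model an \code{NTFModel}.
#' @param eq the \code{NTFEquilibrium} for \code{model}.
#' @param relationship see above.
#' @param sex1,sex2 \code{"m"} or \code{"f"}.
#' @return a 2x2 numeric matrix.
#' @export
pairCovariance <- function(model, eq,
                           relationship = c("self", "spouse", "MZ", "DZ",
                                            "sib", "parent_offspring"),
                           sex1 = "m", sex2 = sex1) {
  relationship <- match.arg(relationship)
  stopifnot(is(model, "NTFModel"), is(eq, "NTFEquilibrium"))
  if (!eq@converged) stop("equilibrium has not converged")
  s1 <- match.arg(sex1, c("m", "f")); s2 <- match.arg(sex2, c("m", "f"))
  if (relationship == "self" && s1 != s2)
    stop("'self' requires equal sexes")
  if (relationship == "spouse" && !(s1 == "m" && s2 == "f"))
    stop("'spouse' expects sex1 = 'm' (husband rows), sex2 = 'f'")
  if (relationship == "MZ" && s1 != s2)
    stop("MZ co-twins have equal sexes")
  .pair_cov_mats(.model_mats(model), .eq_list(eq), relationship, s1, s2)
}

# ---- family configurations ---------------------------------------------

#' Describe the membership of one family
#'
#' @param roles character vector from \{father, mother, twin1, twin2,
#'   sib1, sib2, ...\}; labels must be unique.
#' @param sexes \code{"m"}/\code{"f"} per role.
#' @param zygosity \code{"MZ"}, \code{"DZ"} or \code{"none"} (no twin pair).
#' @return a list of class \code{ntfFamilyConfig}.
#' @export
familyConfiguration <- function(roles, sexes, zygosity = "none") {
  roles <- as.character(roles); sexes <- as.character(sexes)
  if (!length(roles)) stop("at least one role must be present")
  if (anyDuplicated(roles)) stop("role labels must be unique within a family")
  if (length(sexes) != length(roles)) stop("sexes must match roles")
  ok <- grepl("^(father|mother|twin[12]|sib[0-9]+)$", roles)
  if (!all(ok)) stop("unknown role(s): ", paste(roles[!ok], collapse = ", "))
  if (!all(sexes %in% c("m", "f"))) stop("sexes must be 'm' or 'f'")
  if (any(roles == "father") && sexes[roles == "father"] != "m")
    stop("father must be male")
  if (any(roles == "mother") && sexes[roles == "mother"] != "f")
    stop("mother must be female")
  if (!(zygosity %in% c("MZ", "DZ", "none"))) stop("invalid zygosity")
  tw <- roles %in% c("twin1", "twin2")
  if (sum(tw) > 0 && zygosity == "none")
    stop("twin roles require zygosity MZ or DZ")
  if (zygosity == "MZ" && sum(tw) == 2 && length(unique(sexes[tw])) != 1)
    stop("MZ co-twins must have equal sexes")
  ord <- order(match(roles, c("father", "mother", "twin1", "twin2",
                              paste0("sib", 1:50))))
  structure(list(roles = roles[ord], sexes = sexes[ord], zygosity = zygosity),
            class = "ntfFamilyConfig")
}

# relationship (and orientation) between two roles of one configuration;
# swap = TRUE when the block must be computed with arguments reversed and
# transposed.
.pair_rel <- function(r1, r2, zyg) {
  isPar <- function(r) r %in% c("father", "mother")
  isTwin <- function(r) r %in% c("twin1", "twin2")
  if (isPar(r1) && isPar(r2)) {
    if (r1 == "father") list(rel = "spouse", swap = FALSE)
    else list(rel = "spouse", swap = TRUE)
  } else if (isPar(r1) && !isPar(r2)) {
    list(rel = "parent_offspring", swap = TRUE)
  } else if (!isPar(r1) && isPar(r2)) {
    list(rel = "parent_offspring", swap = FALSE)
  } else if (isTwin(r1) && isTwin(r2)) {
    list(rel = if (zyg == "MZ") "MZ" else "DZ", swap = FALSE)
  } else {
    list(rel = "sib", swap = FALSE)
  }
}

# Precompiled assembly recipe for one configuration: for every member the
# self-block key, for every member pair the block key and orientation.
# Block keys are "rel|sex1|sex2" strings shared across configurations so
# each distinct block is computed once per parameter vector.
.config_recipe <- function(config) {
  k <- length(config$roles)
  selfKeys <- paste("self", config$sexes, config$sexes, sep = "|")
  pairs <- list()
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    pr <- .pair_rel(config$roles[i], config$roles[j], config$zygosity)
    key <- if (pr$swap)
      paste(pr$rel, config$sexes[j], config$sexes[i], sep = "|")
    else
      paste(pr$rel, config$sexes[i], config$sexes[j], sep = "|")
    pairs[[length(pairs) + 1L]] <- list(i = i, j = j, key = key,
                                        swap = pr$swap)
  }
  list(k = k, sexes = config$sexes, selfKeys = selfKeys, pairs = pairs,
       keys = unique(c(selfKeys, vapply(pairs, `[[`, "", "key"))))
}

.block_dict <- function(mats, eq, keys) {
  out <- vector("list", length(keys))
  names(out) <- keys
  for (key in keys) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    out[[key]] <- .pair_cov_mats(mats, eq, p[1], p[2], p[3])
  }
  out
}

.assemble_sigma <- function(recipe, dict) {
  k <- recipe$k
  S <- matrix(0, 2 * k, 2 * k)
  for (i in seq_len(k)) {
    ii <- (2 * i - 1):(2 * i)
    S[ii, ii] <- dict[[recipe$selfKeys[i]]]
  }
  for (p in recipe$pairs) {
    ii <- (2 * p$i - 1):(2 * p$i); jj <- (2 * p$j - 1):(2 * p$j)
    B <- dict[[p$key]]
    if (p$swap) B <- t(B)
    S[ii, jj] <- B
    S[jj, ii] <- t(B)
  }
  S
}

#' Joint mean vector and covariance matrix for one family configuration
#'
#' Assembles the model-implied moments of the stacked trait vector
#' (2 traits per member, members ordered father, mother, twin1, twin2,
#' sib1, ...) from \code{\link{pairCovariance}} blocks and the means model.
#'
#' @param model an \code{NTFModel}.
#' @param eq its \code{NTFEquilibrium}.
#' @param config an \code{\link{familyConfiguration}}.
#' @return list with \code{mean} (length 2k) and \code{sigma} (2k x 2k,
#'   symmetric), plus \code{labels}.
#' @export
familyMoments <- function(model, eq, config) {
  stopifnot(inherits(config, "ntfFamilyConfig"))
  recipe <- .config_recipe(config)
  dict <- .block_dict(.model_mats(model), .eq_list(eq), recipe$keys)
  S <- .assemble_sigma(recipe, dict)
  mn <- as.vector(vapply(config$sexes, function(sx) .member_means(model, sx),
                         numeric(2)))
  labels <- paste(rep(config$roles, each = 2), c("t1", "t2"), sep = ".")
  dimnames(S) <- list(labels, labels)
  names(mn) <- labels
  list(mean = mn, sigma = S, labels = labels)
}
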