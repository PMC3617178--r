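# Generational forward simulation of the generative model: assortative
# mating to equilibrium, Mendelian-style latent transmission, shared
# environments, vertical transmission, and sex-specific effects.  The
# structural equations here are exactly those whose stationary moments the
# analytic core computes, so simulated and analytic moments must agree; the
# simulator is the package's brute-force oracle.

.rmat <- function(n, k = 2, sd = 1) matrix(stats::rnorm(n * k, 0, sd), n, k)

# Phenotype from latent scores for one sex (excluding homogamy C, which is
# assigned at couple formation).
.phen_from_latents <- function(model, sex, G, D, S, T, E, F) {
  L <- .sex_loading(model, sex)
  G %*% t(L) +
    D %*% t(.get_mat(model, paste0("d_", sex))) +
    S %*% t(.get_mat(model, paste0("s_", sex))) +
    T %*% t(.get_mat(model, paste0("t_", sex))) +
    E %*% t(.get_mat(model, paste0("e_", sex))) + F
}

# Copula-based mate matching: returns a permutation of the female pool such
# that the empirical spousal cross-covariance approaches Vp_m mu Vp_f.
# Whitened phenotypes are rotated to canonical axes (SVD), desired wife
# scores are generated from the husbands' scores at the target coupling,
# and actual females are matched to the desired scores by binned rank
# matching; a few refinement rounds correct the residual coupling error.
# eigen-based whitening robust to rank deficiency (e.g. the univariate
# embedding where trait2 carries no variance)
.whiten <- function(P) {
  V <- stats::cov(P)
  ev <- eigen(V, symmetric = TRUE)
  keep <- ev$values > 1e-10 * max(ev$values, 1e-300)
  U <- ev$vectors[, keep, drop = FALSE]
  dinv <- 1 / sqrt(ev$values[keep])
  list(Z = sweep(P, 2, colMeans(P)) %*% U %*% diag(dinv, sum(keep)),
       U = U, dinv = dinv, V = V)
}

.match_mates <- function(Pm, Pf, mu, refine = 2L) {
  n <- nrow(Pm)
  if (all(mu == 0)) return(sample.int(n))
  wh <- .whiten(Pm); ww <- .whiten(Pf)
  Omega <- wh$V %*% mu %*% ww$V
  A <- diag(wh$dinv, length(wh$dinv)) %*% t(wh$U) %*% Omega %*%
    ww$U %*% diag(ww$dinv, length(ww$dinv))
  sv <- svd(A)
  if (max(sv$d) >= 1)
    stop("requested spousal structure is not attainable ",
         "(non-PSD joint spousal covariance)")
  k <- length(sv$d)
  Sh <- wh$Z %*% sv$u; Sw <- ww$Z %*% sv$v
  M <- diag(sv$d, k)                 # target cov(Sh, Sw) in canonical space
  Muse <- M
  nbin <- max(1L, as.integer(floor(sqrt(n) / 2)))
  perm <- seq_len(n)
  for (r in seq_len(refine + 1L)) {
    VE <- diag(k) - crossprod(Muse)
    ev <- eigen(VE, symmetric = TRUE)
    ev$values[ev$values < 1e-10] <- 1e-10
    RE <- ev$vectors %*% diag(sqrt(ev$values), k) %*% t(ev$vectors)
    W <- Sh %*% Muse + .rmat(n, k) %*% RE
    # rank matching of actual female scores to desired scores; with two
    # canonical dimensions, bin on the first and sort within bins
    perm <- integer(n)
    if (k == 1L) {
      perm[order(W[, 1])] <- order(Sw[, 1])
    } else {
      oW <- order(W[, 1]); oS <- order(Sw[, 1])
      bins <- rep(seq_len(nbin), each = ceiling(n / nbin))[seq_len(n)]
      for (b in seq_len(nbin)) {
        iW <- oW[bins == b]; iS <- oS[bins == b]
        perm[iW[order(W[iW, 2])]] <- iS[order(Sw[iS, 2])]
      }
    }
    emp <- crossprod(Sh, Sw[perm, , drop = FALSE]) / (n - 1)
    if (r <= refine) {
      Muse <- Muse + (M - emp)
      s2 <- svd(Muse)
      s2$d <- pmin(s2$d, 0.995)
      Muse <- s2$u %*% diag(s2$d, k) %*% t(s2$v)
    }
  }
  perm
}

#' Simulate a population to mating equilibrium
#'
#' Runs the generative recursion forward: each generation draws latent
#' scores, forms phenotypes, mates the male and female pools (copula
#' matching toward the copath-implied spousal covariance under phenotypic
#' assortment; random pairing plus a shared couple environment C under
#' social homogamy), and produces the next generation by Mendelian-style
#' transmission (offspring additive latents are the midparent value plus a
#' segregation deviate of variance 1/2).  Returns the final mated-pair pool
#' together with the per-generation latent additive (co)variance trajectory.
#'
#' @param model the generating (truth) \code{NTFModel}.
#' @param n couples per generation (at least 1000 for stable matching).
#' @param generations number of generations (15 is ample for equilibrium at
#'   realistic assortment strengths).
#' @param seed mandatory RNG seed.
#' @param refine refinement rounds of the mate matcher.
#' @return a list of class \code{ntfPopulation}: \code{father} and
#'   \code{mother} (each with latent matrices \code{G}, \code{D}, \code{S},
#'   \code{T}, \code{E}, \code{F} and phenotypes \code{P}), \code{C}
#'   (couple-shared environment, homogamy only), \code{trajectory}
#'   (per-generation empirical covariance of the latent additive factors),
#'   and \code{spousalCov} (achieved empirical spousal covariance).
#' @export
simulatePopulation <- function(model, n = 10000L, generations = 15L,
                               seed, refine = 2L) {
  stopifnot(is(model, "NTFModel"), n >= 1000L, generations >= 1L)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  homog <- model@mode == "ABDCTE"
  mu <- if (homog) matrix(0, 2, 2) else .get_mat(model, "mu")
  vfs <- .get_mat(model, "v_fs"); vfd <- .get_mat(model, "v_fd")
  vms <- .get_mat(model, "v_ms"); vmd <- .get_mat(model, "v_md")
  cm <- .get_mat(model, "c_m"); cf <- .get_mat(model, "c_f")

  Gm <- .rmat(n, 4); Gf <- .rmat(n, 4)
  Fm <- matrix(0, n, 2); Ff <- matrix(0, n, 2)
  traj <- vector("list", generations)
  fa <- mo <- NULL; Cc <- NULL; spCov <- NULL
  for (g in seq_len(generations)) {
    Dm <- .rmat(n); Sm <- .rmat(n); Tm <- .rmat(n); Em <- .rmat(n)
    Df <- .rmat(n); Sf <- .rmat(n); Tf <- .rmat(n); Ef <- .rmat(n)
    Pm <- .phen_from_latents(model, "m", Gm, Dm, Sm, Tm, Em, Fm)
    Pf <- .phen_from_latents(model, "f", Gf, Df, Sf, Tf, Ef, Ff)
    perm <- if (homog) sample.int(n) else .match_mates(Pm, Pf, mu, refine)
    Gf <- Gf[perm, , drop = FALSE]; Df <- Df[perm, , drop = FALSE]
    Sf <- Sf[perm, , drop = FALSE]; Tf <- Tf[perm, , drop = FALSE]
    Ef <- Ef[perm, , drop = FALSE]; Ff <- Ff[perm, , drop = FALSE]
    Pf <- Pf[perm, , drop = FALSE]
    if (homog) {
      Cc <- .rmat(n)
      Pm <- Pm + Cc %*% t(cm)
      Pf <- Pf + Cc %*% t(cf)
    }
    fa <- list(G = Gm, D = Dm, S = Sm, T = Tm, E = Em, F = Fm, P = Pm)
    mo <- list(G = Gf, D = Df, S = Sf, T = Tf, E = Ef, F = Ff, P = Pf)
    spCov <- crossprod(sweep(Pm, 2, colMeans(Pm)),
                       sweep(Pf, 2, colMeans(Pf))) / (n - 1)
    # next generation: one son and one daughter per couple
    if (g < generations) {
      Gm <- 0.5 * (fa$G + mo$G) + .rmat(n, 4, sqrt(0.5))
      Gf <- 0.5 * (fa$G + mo$G) + .rmat(n, 4, sqrt(0.5))
      Fm <- fa$P %*% t(vfs) + mo$P %*% t(vms)
      Ff <- fa$P %*% t(vfd) + mo$P %*% t(vmd)
    }
    Gpool <- rbind(if (g < generations) Gm else fa$G,
                   if (g < generations) Gf else mo$G)
    traj[[g]] <- stats::cov(Gpool[, 1:2])
  }
  structure(list(father = fa, mother = mo, C = Cc,
                 trajectory = traj, spousalCov = spCov,
                 model = model, n = n, generations = generations),
            class = "ntfPopulation")
}

# sex of each offspring slot for one family type
.slot_plan <- function(type, nSibs) {
  tw <- switch(type,
               MZM = c("m", "m"), MZF = c("f", "f"),
               DZM = c("m", "m"), DZF = c("f", "f"),
               DZOS = c("m", "f"), SIB = character(0),
               stop("unknown family type: ", type))
  zyg <- switch(type, MZM = "MZ", MZF = "MZ", DZM = "DZ", DZF = "DZ",
                DZOS = "DZ", SIB = "none")
  list(twinSexes = tw, zygosity = zyg, nSibs = nSibs)
}

# row-wise selection between male- and female-path phenotypes
.phen_by_sex <- function(model, sexes, G, D, S, T, E, F, C) {
  cm <- .get_mat(model, "c_m"); cf <- .get_mat(model, "c_f")
  Pm <- .phen_from_latents(model, "m", G, D, S, T, E, F) + C %*% t(cm)
  Pf <- .phen_from_latents(model, "f", G, D, S, T, E, F) + C %*% t(cf)
  male <- sexes == "m"
  out <- Pf
  out[male, ] <- Pm[male, , drop = FALSE]
  out
}

#' Simulate nuclear twin families from an equilibrium parent pool
#'
#' Samples mated pairs with replacement and generates offspring according
#' to the generative recursion: MZ co-twins share identical additive,
#' male-specific and dominance latents; all full siblings share the sibling
#' environment S and (deterministically, given the parents) the familial
#' environment F; twins of a pair additionally share the twin environment T;
#' opposite-sex pairs share D/S/T at correlations r_D/r_S/r_T; unique
#' environments are independent.
#'
#' @param pop an \code{ntfPopulation}.
#' @param design data.frame with columns \code{sample} (label), \code{type}
#'   (\code{MZM, MZF, DZM, DZF, DZOS, SIB}), \code{n} (families),
#'   \code{nSibs} (non-twin siblings per family; random sexes), and
#'   \code{parents} (logical: are parental rows emitted).
#' @param seed RNG seed.
#' @param truthRecords if \code{TRUE}, attach a sidecar data.frame of all
#'   latent component scores per individual (attribute \code{"truth"}).
#' @return a family table data.frame (standardized trait scale; \code{age}
#'   is \code{NA} until \code{\link{applyObservationModel}}).
#' @export
simulateFamilies <- function(pop, design, seed, truthRecords = FALSE) {
  stopifnot(inherits(pop, "ntfPopulation"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  model <- pop$model
  npop <- pop$n
  if (npop < 1L) stop("empty parent pool")
  homog <- model@mode == "ABDCTE"
  rD <- .get_rcor(model, "r_D"); rS <- .get_rcor(model, "r_S")
  rT <- .get_rcor(model, "r_T")
  vfs <- .get_mat(model, "v_fs"); vfd <- .get_mat(model, "v_fd")
  vms <- .get_mat(model, "v_ms"); vmd <- .get_mat(model, "v_md")

  out <- list(); truth <- list(); fidBase <- 0L
  for (r in seq_len(nrow(design))) {
    nf <- design$n[r]
    if (nf < 1) next
    plan <- .slot_plan(design$type[r], design$nSibs[r])
    ci <- sample.int(npop, nf, replace = TRUE)
    faP <- pop$father$P[ci, , drop = FALSE]
    moP <- pop$mother$P[ci, , drop = FALSE]
    faG <- pop$father$G[ci, , drop = FALSE]
    moG <- pop$mother$G[ci, , drop = FALSE]
    Cfam <- if (homog) pop$C[ci, , drop = FALSE] else matrix(0, nf, 2)
    # family-shared factors, sex-specific versions correlated r_X
    mkShared <- function(rho) {
      Zm <- .rmat(nf)
      Zf <- rho * Zm + sqrt(max(0, 1 - rho^2)) * .rmat(nf)
      list(m = Zm, f = Zf)
    }
    ZD <- mkShared(rD); ZS <- mkShared(rS); ZT <- mkShared(rT)
    pick <- function(Z, sexes) {
      out <- Z$f
      out[sexes == "m", ] <- Z$m[sexes == "m", , drop = FALSE]
      out
    }
    fids <- fidBase + seq_len(nf)
    fidBase <- fidBase + nf
    famLabel <- sprintf("%s_%s_%06d", design$sample[r], design$type[r], fids)

    emit <- function(role, sexes, Traits, lat) {
      out[[length(out) + 1L]] <<- data.frame(
        family_id = famLabel, role = role, sex = sexes,
        zygosity = if (role %in% c("twin1", "twin2")) plan$zygosity else "none",
        age = NA_real_, sample = design$sample[r],
        trait1 = Traits[, 1], trait2 = Traits[, 2],
        stringsAsFactors = FALSE)
      if (truthRecords)
        truth[[length(truth) + 1L]] <<- data.frame(
          family_id = famLabel, role = role,
          A1 = lat$G[, 1], A2 = lat$G[, 2], B1 = lat$G[, 3], B2 = lat$G[, 4],
          D1 = lat$D[, 1], D2 = lat$D[, 2], S1 = lat$S[, 1], S2 = lat$S[, 2],
          T1 = lat$T[, 1], T2 = lat$T[, 2], E1 = lat$E[, 1], E2 = lat$E[, 2],
          F1 = lat$F[, 1], F2 = lat$F[, 2], C1 = lat$C[, 1], C2 = lat$C[, 2],
          stringsAsFactors = FALSE)
    }

    if (design$parents[r]) {
      z2 <- matrix(0, nf, 2)
      emit("father", rep("m", nf), faP,
           list(G = faG, D = pop$father$D[ci, , drop = FALSE],
                S = pop$father$S[ci, , drop = FALSE],
                T = pop$father$T[ci, , drop = FALSE],
                E = pop$father$E[ci, , drop = FALSE],
                F = pop$father$F[ci, , drop = FALSE], C = Cfam))
      emit("mother", rep("f", nf), moP,
           list(G = moG, D = pop$mother$D[ci, , drop = FALSE],
                S = pop$mother$S[ci, , drop = FALSE],
                T = pop$mother$T[ci, , drop = FALSE],
                E = pop$mother$E[ci, , drop = FALSE],
                F = pop$mother$F[ci, , drop = FALSE], C = Cfam))
    }

    makeOffspring <- function(sexes, isTwin, copyOf = NULL) {
      # copyOf: latents of the MZ co-twin to replicate (G and D identical)
      G <- if (is.null(copyOf)) 0.5 * (faG + moG) + .rmat(nf, 4, sqrt(0.5))
           else copyOf$G
      D <- if (is.null(copyOf)) 0.5 * pick(ZD, sexes) + sqrt(0.75) * .rmat(nf)
           else copyOf$D
      S <- pick(ZS, sexes)
      T <- if (isTwin) pick(ZT, sexes) else .rmat(nf)
      E <- .rmat(nf)
      F <- matrix(0, nf, 2)
      if (model@mode == "ABDFTE") {
        male <- sexes == "m"
        F[male, ] <- faP[male, , drop = FALSE] %*% t(vfs) +
                     moP[male, , drop = FALSE] %*% t(vms)
        F[!male, ] <- faP[!male, , drop = FALSE] %*% t(vfd) +
                      moP[!male, , drop = FALSE] %*% t(vmd)
      }
      lat <- list(G = G, D = D, S = S, T = T, E = E, F = F, C = Cfam)
      lat$P <- .phen_by_sex(model, sexes, G, D, S, T, E, F, Cfam)
      lat
    }

    if (length(plan$twinSexes)) {
      s1 <- rep(plan$twinSexes[1], nf); s2 <- rep(plan$twinSexes[2], nf)
      tw1 <- makeOffspring(s1, isTwin = TRUE)
      tw2 <- makeOffspring(s2, isTwin = TRUE,
                           copyOf = if (plan$zygosity == "MZ") tw1 else NULL)
      emit("twin1", s1, tw1$P, tw1)
      emit("twin2", s2, tw2$P, tw2)
    }
    if (plan$nSibs > 0) for (s in seq_len(plan$nSibs)) {
      sx <- sample(c("m", "f"), nf, replace = TRUE)
      sb <- makeOffspring(sx, isTwin = FALSE)
      emit(paste0("sib", s), sx, sb$P, sb)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (truthRecords) attr(res, "truth") <- do.call(rbind, truth)
  res
}
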