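# Observation model: ages, covariate effects on raw scales, outliers and
# missingness, emulating the structure of multi-sample twin-family studies
# (IQ-like and height-like raw scales).

#' Configuration of the observation model
#'
#' @param ageRange list with elements \code{twin}, \code{sib}, \code{parent}
#'   giving uniform age ranges in years (twins of a pair share one age).
#' @param coef list with elements \code{trait1} and \code{trait2}, each a
#'   named vector \code{c(intercept, sex, age, age2, sd)}: raw score =
#'   intercept + sex male indicator effect + age and age-squared effects +
#'   sd times the standardized model score.  Defaults give an IQ-like scale
#'   (mean 100, SD 12) and a height-like centimetre scale.
#' @param outlierRate per-score probability of replacing a value with a
#'   gross outlier more than 4 SD from the mean.
#' @param exactOutliers \code{NULL}, or a list
#'   \code{list(trait = "trait2", neg = 8, pos = 2)} to inject exact counts
#'   of negative/positive gross outliers into one trait.
#' @param missingRate per-score missingness probability, a scalar or a named
#'   vector with elements \code{twin}, \code{sib}, \code{parent}.
#' @return list of class \code{ntfObsConfig}.
#' @export
obsModelConfig <- function(
    ageRange = list(twin = c(12, 28), sib = c(10, 35), parent = c(29, 78)),
    coef = list(
      trait1 = c(intercept = 100, sex = 1.5, age = 0.25, age2 = -0.004,
                 sd = 12),
      trait2 = c(intercept = 162, sex = 12, age = 0.35, age2 = -0.005,
                 sd = 7)),
    outlierRate = 0, exactOutliers = NULL, missingRate = 0) {
  stopifnot(outlierRate >= 0, outlierRate <= 1)
  structure(list(ageRange = ageRange, coef = coef,
                 outlierRate = outlierRate, exactOutliers = exactOutliers,
                 missingRate = missingRate),
            class = "ntfObsConfig")
}

.role_class <- function(role) {
  ifelse(role %in% c("father", "mother"), "parent",
         ifelse(role %in% c("twin1", "twin2"), "twin", "sib"))
}

#' Map standardized simulated traits onto raw observation scales
#'
#' Assigns ages (uniform within role-specific ranges; co-twins share an
#' age), applies sex, age and age-squared effects plus the raw-scale
#' location and spread, and optionally injects gross outliers (by
#' construction at least 4 SD from the clean mean) and missingness.  The
#' inverse of the phenotype-adjustment step of the analysis pipeline.
#'
#' @param fam a family table from \code{\link{simulateFamilies}}.
#' @param config an \code{\link{obsModelConfig}}.
#' @param seed RNG seed.
#' @return the family table on raw scales, with attribute
#'   \code{"outlierLog"} (data.frame: trait, sign, count).
#' @export
applyObservationModel <- function(fam, config = obsModelConfig(), seed) {
  stopifnot(inherits(config, "ntfObsConfig"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- nrow(fam)
  rc <- .role_class(fam$role)
  age <- numeric(n)
  for (cl in c("twin", "sib", "parent")) {
    sel <- rc == cl
    rg <- config$ageRange[[cl]]
    age[sel] <- stats::runif(sum(sel), rg[1], rg[2])
  }
  # co-twins share one age: copy twin1's age onto twin2 within family
  t1 <- fam$role == "twin1"; t2 <- fam$role == "twin2"
  m <- match(fam$family_id[t2], fam$family_id[t1])
  age[t2] <- ifelse(is.na(m), age[t2], age[t1][m])
  fam$age <- round(age, 1)

  male <- fam$sex == "m"
  olog <- data.frame(trait = character(0), sign = character(0),
                     count = integer(0), stringsAsFactors = FALSE)
  for (tr in c("trait1", "trait2")) {
    b <- config$coef[[tr]]
    z <- fam[[tr]]
    raw <- b["intercept"] + b["sex"] * male + b["age"] * fam$age +
      b["age2"] * fam$age^2 + b["sd"] * z
    cmean <- mean(raw, na.rm = TRUE); csd <- stats::sd(raw, na.rm = TRUE)
    inject <- function(idx, sign) {
      mag <- (4.3 + abs(stats::rnorm(length(idx), 0, 0.5))) * csd
      raw[idx] <<- cmean + sign * mag
    }
    nneg <- npos <- 0L
    if (config$outlierRate > 0) {
      hit <- which(stats::runif(n) < config$outlierRate & !is.na(raw))
      sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
      inject(hit[sgn < 0], -1); inject(hit[sgn > 0], 1)
      nneg <- sum(sgn < 0); npos <- sum(sgn > 0)
    }
    eo <- config$exactOutliers
    if (!is.null(eo) && eo$trait == tr) {
      pool <- which(!is.na(raw))
      idx <- sample(pool, eo$neg + eo$pos)
      inject(idx[seq_len(eo$neg)], -1)
      if (eo$pos > 0) inject(idx[eo$neg + seq_len(eo$pos)], 1)
      nneg <- nneg + eo$neg; npos <- npos + eo$pos
    }
    if (nneg + npos > 0)
      olog <- rbind(olog,
                    data.frame(trait = tr, sign = c("neg", "pos"),
                               count = c(nneg, npos)))
    fam[[tr]] <- round(raw, 2)
  }
  mr <- config$missingRate
  if (any(mr > 0)) {
    rate <- if (length(mr) == 1) rep(mr, n) else unname(mr[rc])
    for (tr in c("trait1", "trait2"))
      fam[[tr]][stats::runif(n) < rate] <- NA
  }
  attr(fam, "outlierLog") <- olog
  fam
}
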