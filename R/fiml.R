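# Full-information maximum likelihood over families with arbitrary
# per-member missingness.

.ft_cols <- c("family_id", "role", "sex", "zygosity", "age", "sample",
              "trait1", "trait2")

.norm_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- ifelse(x %in% c("m", "male", "1"), "m",
                ifelse(x %in% c("f", "female", "2"), "f", NA))
  if (anyNA(out)) stop("unrecognised sex codes")
  out
}

#' Read / write the delimited family-table format
#'
#' One row per individual with header columns \code{family_id, role, sex,
#' zygosity, age, sample, trait1, trait2}; \code{NA} marks missing values.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a validated data.frame.
#' @export
readFamilyTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validateFamilyTable(df)
}

#' @rdname readFamilyTable
#' @param df a family-table data.frame.
#' @export
writeFamilyTable <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readFamilyTable
#' @export
validateFamilyTable <- function(df) {
  miss <- setdiff(.ft_cols, names(df))
  if (length(miss))
    stop("family table is missing column(s): ", paste(miss, collapse = ", "))
  df$sex <- .norm_sex(df$sex)
  df$zygosity[is.na(df$zygosity)] <- "none"
  if (!all(df$zygosity %in% c("MZ", "DZ", "none")))
    stop("zygosity must be MZ, DZ or none")
  df
}

# Group families by configuration + missingness pattern so that one
# covariance factorisation serves every family sharing the pattern, and
# reduce each group's data to sufficient statistics (crossproduct and
# column sums), making the likelihood cost independent of family count.
# Results are independent of the grouping by construction (the likelihood
# is a sum over families).
.prepare_families <- function(data) {
  data <- validateFamilyTable(data)
  fams <- split(seq_len(nrow(data)), data$family_id)
  cfgKey <- character(0); cfgs <- list()
  grpKey <- character(0)
  grpCfg <- integer(0); grpMask <- list(); grpRows <- list()
  nDroppedEmpty <- 0L
  for (fr in fams) {
    roles <- data$role[fr]; sexes <- data$sex[fr]
    zyg <- if (any(roles %in% c("twin1", "twin2")))
      data$zygosity[fr][which(roles %in% c("twin1", "twin2"))[1]] else "none"
    ord <- order(match(roles, c("father", "mother", "twin1", "twin2",
                                paste0("sib", 1:50))))
    fr <- fr[ord]; roles <- roles[ord]; sexes <- sexes[ord]
    y <- as.vector(rbind(data$trait1[fr], data$trait2[fr]))
    mask <- !is.na(y)
    if (!any(mask)) { nDroppedEmpty <- nDroppedEmpty + 1L; next }
    ck <- paste(roles, sexes, zyg, collapse = "|")
    ci <- match(ck, cfgKey)
    if (is.na(ci)) {
      cfgKey <- c(cfgKey, ck)
      cfgs[[length(cfgs) + 1L]] <- familyConfiguration(roles, sexes, zyg)
      ci <- length(cfgs)
    }
    gk <- paste(ck, paste(as.integer(mask), collapse = ""), sep = "#")
    gi <- match(gk, grpKey)
    if (is.na(gi)) {
      grpKey <- c(grpKey, gk)
      gi <- length(grpKey)
      grpCfg[gi] <- ci
      grpMask[[gi]] <- mask
      grpRows[[gi]] <- list()
    }
    grpRows[[gi]][[length(grpRows[[gi]]) + 1L]] <- y[mask]
  }
  recipes <- lapply(cfgs, .config_recipe)
  allKeys <- unique(unlist(lapply(recipes, `[[`, "keys")))
  groups <- lapply(seq_along(grpKey), function(g) {
    X <- do.call(rbind, grpRows[[g]])
    list(config = grpCfg[g], mask = grpMask[[g]], n = nrow(X),
         M = crossprod(X), cs = colSums(X))
  })
  list(configs = cfgs, recipes = recipes, allKeys = allKeys,
       groups = groups, nDroppedEmpty = nDroppedEmpty)
}

# -2 log-likelihood given a solved equilibrium; Inf on singular blocks.
.negloglik_prepared <- function(model, eq, prep) {
  .negloglik_core(.model_mats(model),
                  list(m = .member_means(model, "m"),
                       f = .member_means(model, "f")),
                  eq, prep)
}

.negloglik_core <- function(mats, meansBySex, eq, prep) {
  eq <- .eq_list(eq)
  dict <- .block_dict(mats, eq, prep$allKeys)
  sigmas <- lapply(prep$recipes, .assemble_sigma, dict = dict)
  means <- lapply(prep$recipes, function(rc)
    as.vector(unlist(meansBySex[rc$sexes], use.names = FALSE)))
  total <- 0
  log2pi <- log(2 * pi)
  for (g in prep$groups) {
    S <- sigmas[[g$config]][g$mask, g$mask, drop = FALSE]
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    mu <- means[[g$config]][g$mask]
    # tr(Sigma^-1 (X-mu)'(X-mu)) from sufficient statistics
    A <- if (all(mu == 0)) g$M
         else g$M - tcrossprod(g$cs, mu) - tcrossprod(mu, g$cs) +
           g$n * tcrossprod(mu)
    quad <- sum(chol2inv(R) * A)
    kobs <- length(mu)
    logdet <- 2 * sum(log(diag(R)))
    total <- total + g$n * (kobs * log2pi + logdet) + quad
  }
  total
}

#' Raw-data (FIML) -2 log-likelihood of a model on a family table
#'
#' Sums, over families, k_obs log(2 pi) + log det Sigma_obs +
#' (x - mu_obs)' Sigma_obs^-1 (x - mu_obs), where Sigma_obs and mu_obs are
#' the model-implied family moments restricted to the observed entries.
#' Families whose trait values are all missing are dropped (their count is
#' reported as an attribute); a member with both traits missing contributes
#' nothing, so deleting such a member leaves the value unchanged.
#'
#' @param model an \code{NTFModel}.
#' @param data a family table (see \code{\link{readFamilyTable}}).
#' @param eq optionally a pre-solved \code{NTFEquilibrium}.
#' @return scalar -2 log-likelihood with attribute \code{nDroppedEmpty}.
#' @export
fimlNegLogLik <- function(model, data, eq = NULL) {
  prep <- .prepare_families(data)
  if (is.null(eq)) eq <- solveEquilibrium(model)
  val <- .negloglik_prepared(model, eq, prep)
  attr(val, "nDroppedEmpty") <- prep$nDroppedEmpty
  val
}
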