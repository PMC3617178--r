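# Model construction and the free-parameter registry.

.lower_cells <- list(c(1L, 1L), c(2L, 1L), c(2L, 2L))
.full_cells  <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))

.active_mats <- function(mode) {
  common <- c("a_m", "a_f", "b", "d_m", "d_f", "t_m", "t_f", "e_m", "e_f")
  switch(mode,
    ABDSTE = c(common, "s_m", "s_f", "mu"),
    ABDFTE = c(common, "v_fs", "v_fd", "v_ms", "v_md", "mu"),
    ABDCTE = c(common, "c_m", "c_f"))
}

.active_rcors <- function(mode) {
  switch(mode,
    ABDSTE = c("r_D", "r_S", "r_T"),
    ABDFTE = c("r_D", "r_T"),
    ABDCTE = c("r_D", "r_T"))
}

# default starting values by matrix family
.default_value <- function(mat, i, j) {
  if (mat == "mu") return(if (i == j) 0.05 else 0.02)
  if (mat %in% c("v_fs", "v_fd", "v_ms", "v_md")) return(0.05)
  base <- switch(substr(mat, 1, 1),
                 a = 0.6, b = 0.2, d = 0.3, s = 0.3, t = 0.3, e = 0.5,
                 c = 0.3, 0.1)
  if (i == j) base else 0.05
}

.default_bounds <- function(mat, i, j) {
  if (mat == "mu") return(c(-0.95, 0.95))
  if (mat %in% c("v_fs", "v_fd", "v_ms", "v_md")) return(c(-2, 2))
  if (mat == "rcor") return(c(-1, 1))
  if (mat == "mean") return(c(-3, 3))
  if (i == j) c(0, 3) else c(-3, 3)
}

.registry_row <- function(param, mat, i, j, value, free) {
  b <- .default_bounds(mat, i, j)
  data.frame(param = param, mat = mat, i = i, j = j, value = value,
             free = free, lower = b[1], upper = b[2], group = param,
             stringsAsFactors = FALSE)
}

.build_registry <- function(mode) {
  rows <- list()
  for (m in .active_mats(mode)) {
    cells <- if (m %in% .cholesky_mats) .lower_cells else .full_cells
    for (cl in cells) {
      pn <- sprintf("%s_%d%d", m, cl[1], cl[2])
      rows[[pn]] <- .registry_row(pn, m, cl[1], cl[2],
                                  .default_value(m, cl[1], cl[2]), TRUE)
    }
  }
  for (r in .active_rcors(mode))
    rows[[r]] <- .registry_row(r, "rcor", 1L, 1L, 0.9, TRUE)
  do.call(rbind, rows)
}

.add_means <- function(reg, meansModel) {
  if (meansModel == "zero") return(reg)
  nms <- if (meansModel == "trait") c("mean_1", "mean_2")
         else c("mean_m_1", "mean_m_2", "mean_f_1", "mean_f_2")
  for (k in seq_along(nms)) {
    tr <- as.integer(sub(".*_(\\d)$", "\\1", nms[k]))
    reg <- rbind(reg, .registry_row(nms[k], "mean", tr, 1L, 0, TRUE))
  }
  reg
}

.expand_drop <- function(reg, d) {
  # "t" expands to t_m and t_f; "mu", "b", "v" are single/4-matrix names
  if (d == "v") return(intersect(c("v_fs", "v_fd", "v_ms", "v_md"),
                                 unique(reg$mat)))
  hit <- unique(reg$mat)[unique(reg$mat) %in%
                           c(d, paste0(d, "_m"), paste0(d, "_f"))]
  hit
}

#' Build a nuclear twin family model variant
#'
#' Constructs a fully specified \code{\link{NTFModel}}: the mode selects
#' which latent sources are active (see \code{\linkS4class{NTFModel}}), and
#' structural edits shape the free-parameter registry.  Editing supports the
#' whole model-selection ladder: dropping entire 2x2 matrices in an
#' all-or-none manner, fixing single cells (e.g. a cross-sex correlation to
#' 1), and equating cells (e.g. the two cross-trait copaths).
#'
#' @param mode \code{"ABDSTE"}, \code{"ABDFTE"} or \code{"ABDCTE"}.
#' @param drop character vector of matrix names to fix to zero wholesale;
#'   a bare family name (\code{"t"}) covers both sex-specific matrices,
#'   \code{"v"} covers all four vertical-transmission matrices.
#' @param fix named list of single-cell fixes, e.g.
#'   \code{list(r_S = 1, a_m_21 = 0)}.
#' @param equate list of character vectors of parameter names to constrain
#'   equal, e.g. \code{list(c("mu_12", "mu_21"))}.
#' @param sexEqual logical; if \code{TRUE}, equate every male/female path
#'   pair, drop the male-specific B factor, and fix all cross-sex
#'   correlations to 1 (no sex limitation at all).
#' @param values named numeric vector of starting values to overwrite
#'   defaults (applied before edits).
#' @param constrainQ logical; restrict fits to the surface where the
#'   equilibrium q off-diagonal is zero (gametic-phase-disequilibrium test).
#' @param meansModel \code{"zero"} (default, for standardized residual
#'   traits), \code{"trait"} or \code{"trait_sex"}.
#' @return an \code{NTFModel}.
#' @examples
#' m <- ntfModel("ABDSTE", drop = "t")
#' nFreeParams(m)
#' @export
ntfModel <- function(mode = c("ABDSTE", "ABDFTE", "ABDCTE"),
                     drop = character(0), fix = list(), equate = list(),
                     sexEqual = FALSE, values = NULL,
                     constrainQ = FALSE, meansModel = "zero") {
  mode <- match.arg(mode)
  reg <- .build_registry(mode)
  reg <- .add_means(reg, meansModel)
  if (!is.null(values)) {
    unknown <- setdiff(names(values), reg$param)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    reg$value[match(names(values), reg$param)] <- unname(values)
  }
  model <- new("NTFModel", mode = mode, params = reg,
               constrainQ = constrainQ, meansModel = meansModel)
  if (sexEqual) {
    if ("b" %in% reg$mat) drop <- union(drop, "b")
    pairs <- list(c("a_m", "a_f"), c("d_m", "d_f"), c("s_m", "s_f"),
                  c("t_m", "t_f"), c("e_m", "e_f"), c("c_m", "c_f"),
                  c("v_fs", "v_fd"), c("v_ms", "v_md"))
    for (pr in pairs) {
      if (!all(pr %in% reg$mat)) next
      cells <- if (pr[1] %in% .cholesky_mats) .lower_cells else .full_cells
      for (cl in cells)
        equate <- c(equate, list(sprintf("%s_%d%d", pr, cl[1], cl[2])))
    }
    for (r in .active_rcors(mode)) fix[[r]] <- 1
  }
  reduceModel(model, drop = drop, fix = fix, equate = equate)
}

#' Derive a nested submodel by structural edits
#'
#' Applies drops (matrix fixed to zero), fixes (single cells), equality
#' constraints, or the constrained-equilibrium edit forcing the q
#' off-diagonal to zero, producing a submodel nested in \code{model}.
#'
#' @param model an \code{NTFModel}.
#' @inheritParams ntfModel
#' @param constrainQ if \code{TRUE}, restrict fits to parameter points whose
#'   equilibrium satisfies q[1,2] = 0 (counts as one constraint against k).
#' @return an \code{NTFModel} with a reduced free-parameter registry.
#' @export
reduceModel <- function(model, drop = character(0), fix = list(),
                        equate = list(), constrainQ = model@constrainQ) {
  stopifnot(is(model, "NTFModel"))
  reg <- model@params
  for (d in drop) {
    mats <- .expand_drop(reg, d)
    if (!length(mats))
      stop("drop edit names an inactive matrix: ", d)
    sel <- reg$mat %in% mats
    reg$value[sel] <- 0
    reg$free[sel] <- FALSE
    reg$group[sel] <- reg$param[sel]
  }
  if (length(fix)) {
    unknown <- setdiff(names(fix), reg$param)
    if (length(unknown))
      stop("fix edit names unknown parameter(s): ",
           paste(unknown, collapse = ", "))
    for (nm in names(fix)) {
      k <- match(nm, reg$param)
      val <- fix[[nm]]
      if (reg$i[k] == reg$j[k] && reg$mat[k] %in% .cholesky_mats && val < 0)
        stop("cannot fix a path-matrix diagonal to a negative value")
      reg$value[k] <- val
      reg$free[k] <- FALSE
      reg$group[k] <- reg$param[k]
    }
  }
  for (grp in equate) {
    idx <- match(grp, reg$param)
    if (anyNA(idx))
      stop("equate edit names unknown parameter(s): ",
           paste(grp[is.na(idx)], collapse = ", "))
    idx <- idx[reg$free[idx]]
    if (length(idx) < 2) next
    reg$group[idx] <- reg$group[idx[1]]
    reg$value[idx] <- reg$value[idx[1]]
  }
  new("NTFModel", mode = model@mode, params = reg,
      constrainQ = constrainQ, meansModel = model@meansModel)
}

# ---- parameter vector packing ------------------------------------------

.free_groups <- function(model) {
  reg <- model@params
  unique(reg$group[reg$free])
}

.pack_theta <- function(model) {
  reg <- model@params
  g <- .free_groups(model)
  idx <- match(g, reg$group)
  theta <- reg$value[idx]
  names(theta) <- g
  attr(theta, "lower") <- reg$lower[idx]
  attr(theta, "upper") <- reg$upper[idx]
  theta
}

.unpack_theta <- function(model, theta) {
  reg <- model@params
  g <- .free_groups(model)
  reg$value[reg$free] <- theta[match(reg$group[reg$free], g)]
  model@params <- reg
  model
}

.get_mat <- function(model, name) {
  reg <- model@params
  sel <- reg$mat == name
  M <- matrix(0, 2, 2)
  if (any(sel)) M[cbind(reg$i[sel], reg$j[sel])] <- reg$value[sel]
  M
}

.get_rcor <- function(model, name) {
  k <- match(name, model@params$param)
  if (is.na(k)) 1 else model@params$value[k]
}

# Means vector (length 2) for a member of given sex.
.member_means <- function(model, sex) {
  reg <- model@params
  mm <- model@meansModel
  if (mm == "zero") return(c(0, 0))
  if (mm == "trait")
    return(c(reg$value[match("mean_1", reg$param)],
             reg$value[match("mean_2", reg$param)]))
  pre <- if (sex == "m") "mean_m_" else "mean_f_"
  c(reg$value[match(paste0(pre, 1), reg$param)],
    reg$value[match(paste0(pre, 2), reg$param)])
}

# ---- methods ------------------------------------------------------------

#' @rdname pathMatrix
#' @export
setMethod("pathMatrix", "NTFModel", function(object, name) {
  .get_mat(object, name)
})

#' @rdname nFreeParams
#' @export
setMethod("nFreeParams", "NTFModel", function(object) {
  length(.free_groups(object)) - as.integer(object@constrainQ)
})

setMethod("show", "NTFModel", function(object) {
  reg <- object@params
  cat(sprintf("NTFModel variant %s (%s mating)\n", object@mode,
              if (object@mode == "ABDCTE") "social-homogamy"
              else "phenotypic-assortment"))
  cat(sprintf("  free parameters: %d%s\n", nFreeParams(object),
              if (object@constrainQ) " (q off-diagonal constrained to 0)"
              else ""))
  act <- setdiff(unique(reg$mat), c("rcor", "mean"))
  dropped <- vapply(act, function(m)
    all(!reg$free[reg$mat == m] & reg$value[reg$mat == m] == 0), logical(1))
  cat("  active matrices:", paste(act[!dropped], collapse = " "), "\n")
  if (any(dropped))
    cat("  dropped matrices:", paste(act[dropped], collapse = " "), "\n")
  cat("  means model:", object@meansModel, "\n")
  invisible(object)
})

#' Build a model variant from a structured configuration file
#'
#' Reads a YAML or JSON file with keys \code{mode}, \code{drop} (vector of
#' matrix names), \code{fix} (map of parameter to value), \code{equate}
#' (list of parameter-name groups), and optionally \code{sexEqual},
#' \code{constrainQ}, \code{meansModel}, \code{values}, and passes them to
#' \code{\link{ntfModel}}.
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return an \code{NTFModel}.
#' @export
ntfModelFromConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be a .yaml/.yml or .json file")
  if (is.null(cfg$mode)) stop("config must name a mode")
  equate <- if (is.null(cfg$equate)) list()
            else lapply(cfg$equate, as.character)
  values <- if (is.null(cfg$values)) NULL else unlist(cfg$values)
  ntfModel(mode = cfg$mode,
           drop = as.character(cfg$drop %||% character(0)),
           fix = as.list(cfg$fix %||% list()),
           equate = equate,
           sexEqual = isTRUE(cfg$sexEqual),
           values = values,
           constrainQ = isTRUE(cfg$constrainQ),
           meansModel = cfg$meansModel %||% "zero")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
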