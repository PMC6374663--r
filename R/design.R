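#' The seven candidate covariate sets
#'
#' Canonical labels for the alternative covariate sets compared in each
#' analysis: intercept only; DBH; DBH + soil; DBH + NCI; DBH + ANCI;
#' DBH + soil + NCI; DBH + soil + ANCI. "soil" always means the triple
#' NMin, P, SBC.
#'
#' @return character vector of set labels.
#' @export
covariate_sets <- function() {
  c("intercept", "dbh", "dbh_soil", "dbh_nci", "dbh_anci",
    "dbh_soil_nci", "dbh_soil_anci")
}

set_has_nci <- function(set) grepl("nci", set)
set_is_asymmetric <- function(set) grepl("anci", set)
set_has_soil <- function(set) grepl("soil", set)
set_has_dbh <- function(set) grepl("dbh", set)

#' Build the per-tree design for one covariate set
#'
#' Assembles standardized model covariates for every tree: z-scored DBH and,
#' when the set includes soil, z-scored NMin, P and SBC interpolated at the
#' tree's location. Standardization is global (pooled across species) and
#' the moments are stored for back-transformation. When the set includes a
#' crowding index, each tree's neighbor list (all trees of any species
#' within `radius` m, same plot) is attached; the index itself is
#' recomputed during sampling because its shape parameters are estimated,
#' so raw index values are divided by the fixed `nci_scale` for sampler
#' conditioning (the index coefficient absorbs the scale).
#'
#' @param trees,soil data frames following the schemas.
#' @param covariate_set one of [covariate_sets()].
#' @param radius neighborhood radius, m.
#' @param kernel distance kernel passed to [compute_nci()].
#' @param nci_scale fixed divisor applied to raw index values.
#' @param k number of soil samples in the interpolation.
#' @return object of class `fruit_design`.
#' @export
build_design <- function(trees, soil = NULL, covariate_set = "dbh",
                         radius = 10, kernel = "as_printed",
                         nci_scale = 100, k = 5) {
  if (!covariate_set %in% covariate_sets())
    stopf("unknown covariate set '%s' (see covariate_sets())", covariate_set)
  n <- nrow(trees)
  species_levels <- sort(unique(trees$species))
  sp <- match(trees$species, species_levels)
  cols <- list("(Intercept)" = rep(1, n))
  moments <- list()
  zscore <- function(x, name) {
    m <- mean(x); s <- sd(x)
    if (!is.finite(s) || s == 0) stopf("covariate %s has zero variance", name)
    moments[[name]] <<- c(mean = m, sd = s)
    (x - m) / s
  }
  if (set_has_dbh(covariate_set))
    cols$dbh <- zscore(trees$dbh_cm, "dbh")
  if (set_has_soil(covariate_set)) {
    if (is.null(soil)) stopf("soil table required for set '%s'", covariate_set)
    interp <- interpolate_soil(soil, trees[c("plot_id", "x_m", "y_m")], k = k)
    sc <- derive_soil_covariates(interp)
    cols$nmin <- zscore(sc$nmin, "nmin")
    cols$p <- zscore(sc$p, "p")
    cols$sbc <- zscore(sc$sbc, "sbc")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  neighbors <- NULL
  if (set_has_nci(covariate_set)) neighbors <- find_neighbors(trees, radius)
  structure(list(
    X = X, species = sp, species_levels = species_levels,
    tree_id = trees$tree_id, dbh_cm = trees$dbh_cm,
    moments = moments, covariate_set = covariate_set,
    has_nci = set_has_nci(covariate_set),
    asymmetric = set_is_asymmetric(covariate_set),
    neighbors = neighbors, kernel = kernel, nci_scale = nci_scale,
    radius = radius), class = "fruit_design")
}

#' @export
print.fruit_design <- function(x, ...) {
  cat("fruit_design [", x$covariate_set, "]: ", nrow(x$X), " trees, ",
      length(x$species_levels), " species, columns: ",
      paste(colnames(x$X), collapse = ", "),
      if (x$has_nci) paste0(" + ", if (x$asymmetric) "ANCI" else "NCI",
                            " (kernel ", x$kernel, ")"), "\n", sep = "")
  invisible(x)
}

#' Covariate audit table
#'
#' One row per tree with its standardized covariates and neighborhood
#' counts, for eyeballing and export (e.g. `write.csv`).
#'
#' @param design a [build_design()] result.
#' @return data frame with `tree_id`, any of `dbh_z`, `nmin_z`, `p_z`,
#'   `sbc_z` present in the design, `n_neighbors`, `n_larger_neighbors`.
#' @export
audit_covariates <- function(design) {
  out <- data.frame(tree_id = design$tree_id, stringsAsFactors = FALSE)
  for (nm in intersect(c("dbh", "nmin", "p", "sbc"), colnames(design$X)))
    out[[paste0(nm, "_z")]] <- design$X[, nm]
  if (is.null(design$neighbors)) {
    out$n_neighbors <- NA_integer_
    out$n_larger_neighbors <- NA_integer_
  } else {
    nb <- design$neighbors
    out$n_neighbors <- tabulate(nb$focal, nrow(design$X))
    out$n_larger_neighbors <- tabulate(nb$focal[nb$larger], nrow(design$X))
  }
  out
}

# Names of the coefficient vector for one species under a design, in the
# order used throughout: fixed columns first, crowding coefficient last.
coef_names <- function(design) {
  nm <- colnames(design$X)
  if (design$has_nci) nm <- c(nm, if (design$asymmetric) "anci" else "nci")
  nm
}

# Restrict a design (and neighbor pairs) to a subset of tree row indices,
# e.g. the reproductive individuals. Standardized columns are re-centered
# and re-scaled over the retained trees so the mean-0/sd-1 invariant holds
# within the analysis; neighbor lists keep all mapped neighbors (only the
# focal set shrinks).
subset_design <- function(design, idx) {
  d <- design
  d$X <- design$X[idx, , drop = FALSE]
  for (nm in names(design$moments)) {
    old <- design$moments[[nm]]
    raw <- d$X[, nm] * old["sd"] + old["mean"]
    m <- mean(raw); s <- sd(raw)
    if (!is.finite(s) || s == 0) stopf("covariate %s degenerate in subset", nm)
    d$X[, nm] <- (raw - m) / s
    d$moments[[nm]] <- c(mean = m, sd = s)
  }
  d$species <- design$species[idx]
  d$tree_id <- design$tree_id[idx]
  d$dbh_cm <- design$dbh_cm[idx]
  keep_sp <- sort(unique(d$species))
  d$species_levels <- design$species_levels[keep_sp]
  d$species <- match(d$species, keep_sp)
  if (!is.null(design$neighbors)) {
    nb <- design$neighbors
    map <- integer(nb$n_trees)
    map[idx] <- seq_along(idx)
    keep <- nb$focal %in% idx
    d$neighbors <- structure(list(
      focal = map[nb$focal[keep]], dbh = nb$dbh[keep], dist = nb$dist[keep],
      larger = nb$larger[keep], neighbor = nb$neighbor[keep],
      n_trees = length(idx), n_clamped = nb$n_clamped),
      class = "neighbor_list")
  }
  d
}
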