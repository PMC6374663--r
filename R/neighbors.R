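#' Find all neighbors within a radius of each mapped tree
#'
#' For each focal tree, lists every other tree of any species within
#' `radius` meters (closed ball: ties at exactly `radius` are included),
#' with Euclidean distances. Pairs are never formed across plots, and
#' neighborhoods are truncated at plot boundaries (no edge correction).
#' Distances below `dist_floor` (coincident or near-coincident stems, e.g.
#' multi-stemmed mapping artifacts) are clamped to the floor so distance
#' kernels stay finite.
#'
#' @param trees data frame following the trees schema.
#' @param radius neighborhood radius in meters (default 10).
#' @param dist_floor minimum distance in meters substituted for closer pairs.
#' @return object of class `neighbor_list`: a list with parallel vectors
#'   `focal` (integer row index into `trees`), `dbh` and `dist` of the
#'   neighbor, and `larger` (neighbor DBH strictly greater than focal DBH),
#'   plus `n_trees` and the clamp count.
#' @export
find_neighbors <- function(trees, radius = 10, dist_floor = 0.1) {
  if (radius <= 0) stopf("radius must be positive")
  if (anyDuplicated(trees$tree_id)) stopf("duplicate tree_id in trees")
  n <- nrow(trees)
  focal <- integer(0); nbr <- integer(0); dd <- numeric(0)
  for (pl in unique(trees$plot_id)) {
    idx <- which(trees$plot_id == pl)
    if (length(idx) < 2) next
    d <- as.matrix(dist(cbind(trees$x_m[idx], trees$y_m[idx])))
    hit <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
    if (!nrow(hit)) next
    i <- idx[hit[, 1]]; j <- idx[hit[, 2]]; dij <- d[hit]
    focal <- c(focal, i, j)
    nbr <- c(nbr, j, i)
    dd <- c(dd, dij, dij)
  }
  clamped <- sum(dd < dist_floor)
  dd <- pmax(dd, dist_floor)
  structure(list(focal = focal,
                 dbh = trees$dbh_cm[nbr],
                 dist = dd,
                 larger = trees$dbh_cm[nbr] > trees$dbh_cm[focal],
                 neighbor = nbr,
                 n_trees = n,
                 n_clamped = clamped),
            class = "neighbor_list")
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat("neighbor_list:", x$n_trees, "trees,", length(x$focal), "pairs",
      sprintf("(mean %.1f neighbors/tree)", length(x$focal) / max(1, x$n_trees)), "\n")
  invisible(x)
}

#' Neighborhood crowding index
#'
#' Crowding on each focal tree is the sum over neighbors of
#' `DBH_i^alpha * exp(-nu / dist_i)` (kernel `"as_printed"`) or
#' `DBH_i^alpha * exp(-nu * dist_i)` (kernel `"decay"`). The asymmetric
#' variant (ANCI) restricts the sum to neighbors with strictly larger DBH
#' than the focal tree, capturing size-asymmetric competition for light.
#' Both kernel forms are provided because the published index, read
#' literally, divides by distance inside the exponent, which *increases*
#' with neighbor distance, while conventional crowding kernels decay with
#' distance; results can be reported under either. `alpha` and `nu` may be
#' scalars or per-species values aligned with `species` (the species index
#' of each focal tree).
#'
#' @param neighbors a [find_neighbors()] result.
#' @param alpha,nu positive kernel parameters (scalar or per-species).
#' @param asymmetric if `TRUE`, only strictly larger neighbors contribute.
#' @param kernel `"as_printed"` (`exp(-nu/dist)`) or `"decay"`
#'   (`exp(-nu*dist)`).
#' @param species optional integer species index per focal tree (needed when
#'   `alpha`/`nu` are per-species vectors).
#' @return numeric vector, one nonnegative index value per tree (0 when the
#'   selected neighbor set is empty).
#' @examples
#' tr <- data.frame(tree_id = 1:2, plot_id = "p", species = "a",
#'                  x_m = c(0, 4), y_m = 0, dbh_cm = c(30, 20))
#' nb <- find_neighbors(tr)
#' compute_nci(nb, alpha = 0.5, nu = 2)[1]  # 20^0.5 * exp(-0.5)
#' @export
compute_nci <- function(neighbors, alpha, nu, asymmetric = FALSE,
                        kernel = c("as_printed", "decay"), species = NULL) {
  kernel <- match.arg(kernel)
  if (any(alpha <= 0) || any(nu < 0)) stopf("alpha must be > 0 and nu >= 0")
  keep <- if (asymmetric) neighbors$larger else rep(TRUE, length(neighbors$focal))
  focal <- neighbors$focal[keep]
  if (length(alpha) > 1 || length(nu) > 1) {
    if (is.null(species)) stopf("species index required for per-species alpha/nu")
    a <- alpha[species[focal]]
    v <- nu[species[focal]]
  } else {
    a <- alpha; v <- nu
  }
  w <- neighbors$dbh[keep]^a *
    exp(if (kernel == "as_printed") -v / neighbors$dist[keep]
        else -v * neighbors$dist[keep])
  out <- numeric(neighbors$n_trees)
  if (length(focal)) {
    s <- rowsum(w, focal)
    out[as.integer(rownames(s))] <- s
  }
  out
}
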