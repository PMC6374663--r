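# Programmatic fixtures shared across test files.

# A small random stem map (single plot unless plots > 1).
tiny_trees <- function(n = 30, seed = 1, plots = 1,
                       species = c("Alpha", "Beta"),
                       width = 41, length = 240) {
  set.seed(seed)
  data.frame(
    tree_id = sprintf("t%04d", seq_len(n)),
    plot_id = paste0("p", sample.int(plots, n, replace = TRUE)),
    species = sample(species, n, replace = TRUE),
    x_m = runif(n, 0, width),
    y_m = runif(n, 0, length),
    dbh_cm = round(runif(n, 5, 80), 1),
    stringsAsFactors = FALSE)
}

# Minimal soil table with s sample points in one plot.
tiny_soil <- function(s = 12, seed = 2, plot_id = "p1",
                      width = 41, length = 240) {
  set.seed(seed)
  data.frame(
    plot_id = plot_id, x_m = runif(s, 0, width), y_m = runif(s, 0, length),
    no3_i = runif(s, 1, 8), nh4_i = runif(s, 2, 12),
    no3_f = runif(s, 5, 16), nh4_f = runif(s, 6, 18),
    p = runif(s, 2, 10), k = runif(s, 40, 120), ca = runif(s, 300, 1200),
    mg = runif(s, 60, 250), stringsAsFactors = FALSE)
}

# A complete small synthetic dataset (default: 4 species x 60 stems).
small_dataset <- function(seed = 1, covariate_set = "dbh", n_species = 4,
                          abundance = 60L, n_plots = 1, ...) {
  spt <- species_table_default()[seq_len(n_species), ]
  spt$abundance <- rep(abundance, n_species)
  truth <- true_params(spt$species, covariate_set, seed = seed, ...)
  simulate_dataset(n_plots = n_plots, species_table = spt, truth = truth,
                   seed = seed)
}

# Fruit observations with latent counts attached.
simulate_fruit_counts_fixture <- function(seed = 12) {
  spt <- species_table_default()[1:3, ]
  spt$abundance <- rep(80L, 3)
  f <- generate_forest(n_plots = 1, species_table = spt, seed = seed)
  truth <- true_params(spt$species, "dbh", seed = seed)
  simulate_fruit(f$trees, f$soil, truth, seed = seed, latent_counts = TRUE)
}

# Independent brute-force neighbor oracle: plain double loop.
brute_force_neighbors <- function(trees, radius = 10) {
  n <- nrow(trees)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- integer(0); dd <- numeric(0)
    for (j in seq_len(n)) {
      if (i == j || trees$plot_id[i] != trees$plot_id[j]) next
      d <- sqrt((trees$x_m[i] - trees$x_m[j])^2 +
                  (trees$y_m[i] - trees$y_m[j])^2)
      if (d <= radius) { hits <- c(hits, j); dd <- c(dd, d) }
    }
    out[[i]] <- list(idx = hits, dist = dd)
  }
  out
}

# Independent k-nearest inverse-distance interpolation oracle.
brute_force_idw <- function(soil, x, y, k = 5) {
  nutr <- c("no3_i", "nh4_i", "no3_f", "nh4_f", "p", "k", "ca", "mg")
  d <- sqrt((soil$x_m - x)^2 + (soil$y_m - y)^2)
  nn <- order(d)[seq_len(min(k, nrow(soil)))]
  if (d[nn[1]] == 0) return(unlist(soil[nn[1], nutr]))
  w <- 1 / d[nn]
  sapply(nutr, function(v) sum(soil[[v]][nn] * w) / sum(w))
}
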