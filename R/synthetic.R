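# Synthetic forest-plot generator.
#
# Emulates the structure of the field study: five 41 m x 240 m mapped
# plots, ~17 focal species with at least 50 stems each and size
# distributions skewed toward small individuals, a soil design of a 1-m
# transect down the plot center plus a 10-m lattice, spatially
# autocorrelated nutrient fields, and three observation periods whose
# ordinal fruit categories are drawn from the package's own generative
# model with known ("true") parameters, so inference can be validated by
# parameter recovery.

#' Plot geometry
#'
#' @param plot_id identifier.
#' @param width,length plot dimensions in meters (default 41 x 240).
#' @return a `plot_geometry` list.
#' @export
plot_geometry <- function(plot_id = "P1", width = 41, length = 240) {
  if (width <= 0 || length <= 0) stopf("plot dimensions must be positive")
  structure(list(plot_id = plot_id, width = width, length = length),
            class = "plot_geometry")
}

#' Default focal-species table
#'
#' Seventeen common canopy and subcanopy species with their census
#' abundances and literature dry seed masses (mg; NA where unavailable),
#' plus lognormal DBH-distribution parameters producing size distributions
#' skewed toward small stems, larger for canopy species.
#'
#' @return data frame with columns `species`, `abundance`, `stature`,
#'   `dbh_meanlog`, `dbh_sdlog`, `seed_mass_mg`.
#' @export
species_table_default <- function() {
  df <- data.frame(
    species = c("Capparis", "Casearia", "Coussarea", "Cryosophila",
                "Dendropanax", "Euterpe", "Faramea", "Goethalsia",
                "Iriartea", "Laetia", "Pentaclethra", "Prestoea",
                "Rinorea", "Socratea", "Virola", "Warszewiczia", "Welfia"),
    abundance = c(74L, 206L, 65L, 114L, 60L, 57L, 85L, 55L, 374L, 48L,
                  367L, 112L, 99L, 198L, 51L, 86L, 173L),
    stature = c("sub", "sub", "sub", "sub", "canopy", "sub", "sub",
                "canopy", "canopy", "canopy", "canopy", "sub", "sub",
                "canopy", "canopy", "sub", "sub"),
    seed_mass_mg = c(721, 1.32, 128, NA, 8.0, 370, NA, 4.3, 3419, 5.2,
                     3697, 167, NA, 3421, 310.4, NA, 1729),
    stringsAsFactors = FALSE)
  df$dbh_meanlog <- ifelse(df$stature == "canopy", log(16), log(9))
  df$dbh_sdlog <- ifelse(df$stature == "canopy", 0.65, 0.5)
  df
}

#' Default soil-field configuration
#'
#' Target mean concentrations for the measured nutrients, mean 30-day
#' mineralization increments for nitrate and ammonium, and the relative
#' magnitudes of the smooth spatial trend and sampling noise. Units are
#' arbitrary concentration units: every soil covariate entering a model is
#' standardized, so units cancel.
#'
#' @param means named nutrient means (`no3_i`, `nh4_i`, `p`, `k`, `ca`, `mg`).
#' @param mineralization named mean incubation increments (`no3`, `nh4`).
#' @param trend_sd standard deviation of the log-scale smooth spatial trend.
#' @param noise_sd relative standard deviation of per-sample noise.
#' @return a `soil_config` list.
#' @export
soil_config <- function(means = c(no3_i = 5, nh4_i = 8, p = 6, k = 80,
                                  ca = 800, mg = 150),
                        mineralization = c(no3 = 6, nh4 = 4),
                        trend_sd = 0.3, noise_sd = 0.1) {
  if (trend_sd < 0 || noise_sd < 0) stopf("soil variances must be >= 0")
  structure(list(means = means, mineralization = mineralization,
                 trend_sd = trend_sd, noise_sd = noise_sd),
            class = "soil_config")
}

# Smooth low-order spatial trend (quadratic surface with random
# coefficients) evaluated at points scaled to the unit square, sd ~ trend_sd.
smooth_trend <- function(x, y, geometry, trend_sd) {
  zx <- (x - geometry$width / 2) / geometry$width
  zy <- (y - geometry$length / 2) / geometry$length
  cf <- rnorm(5)
  f <- cf[1] * zx + cf[2] * zy + cf[3] * zx * zy + cf[4] * (zx^2 - 1 / 12) +
    cf[5] * (zy^2 - 1 / 12)
  f * trend_sd / 0.35  # 0.35 ~ sd of f under unit coefficients
}

# Soil design points for one plot: meter-spaced transect down the plot
# center (composited samples, up to 200 m) plus a 10-m lattice over the
# whole plot.
soil_design_points <- function(geometry) {
  ty <- seq(0.5, by = 1, length.out = min(200L, floor(geometry$length)))
  lat <- expand.grid(x = seq(5, geometry$width, by = 10),
                     y = seq(5, geometry$length, by = 10))
  data.frame(x_m = c(rep(geometry$width / 2, length(ty)), lat$x),
             y_m = c(ty, lat$y))
}

#' Generate mapped stems and soil samples for synthetic plots
#'
#' Places stems uniformly (optionally with Thomas-process clustering)
#' inside each plot, draws DBH from per-species lognormal distributions
#' truncated at the 5-cm census threshold, and samples smooth spatially
#' autocorrelated nutrient fields at the transect + lattice soil design.
#' Identical `(configuration, seed)` reproduces identical tables.
#'
#' @param geometry a [plot_geometry()] (applied to every plot).
#' @param n_plots number of plots.
#' @param species_table as [species_table_default()]; total abundance per
#'   species is split across plots.
#' @param config a [soil_config()].
#' @param seed integer seed.
#' @param clustered if TRUE, stems cluster around Thomas-process parents.
#' @param cluster_sd parent-offspring displacement sd, m.
#' @return list with data frames `trees` and `soil` following the schemas.
#' @export
generate_forest <- function(geometry = plot_geometry(), n_plots = 5,
                            species_table = species_table_default(),
                            config = soil_config(), seed = 1,
                            clustered = FALSE, cluster_sd = 8) {
  if (any(species_table$abundance < 1)) stopf("every species abundance must be >= 1")
  set.seed(derive_seed(seed, 1))
  plots <- paste0("P", seq_len(n_plots))
  trees <- list()
  for (s in seq_len(nrow(species_table))) {
    ab <- species_table$abundance[s]
    alloc <- as.vector(stats::rmultinom(1, ab, rep(1, n_plots)))
    for (pl in seq_len(n_plots)) {
      np <- alloc[pl]
      if (np == 0) next
      if (clustered) {
        n_par <- max(1L, round(np / 8))
        px <- runif(n_par, 0, geometry$width)
        py <- runif(n_par, 0, geometry$length)
        id <- sample.int(n_par, np, replace = TRUE)
        x <- px[id] + rnorm(np, 0, cluster_sd)
        y <- py[id] + rnorm(np, 0, cluster_sd)
        # reflect back into the plot to keep the bounds invariant
        x <- abs(x); x <- geometry$width - abs(geometry$width - x %% (2 * geometry$width))
        y <- abs(y); y <- geometry$length - abs(geometry$length - y %% (2 * geometry$length))
      } else {
        x <- runif(np, 0, geometry$width)
        y <- runif(np, 0, geometry$length)
      }
      u <- runif(np, plnorm(5, species_table$dbh_meanlog[s],
                            species_table$dbh_sdlog[s]), 1)
      dbh <- qlnorm(u, species_table$dbh_meanlog[s], species_table$dbh_sdlog[s])
      trees[[length(trees) + 1L]] <- data.frame(
        plot_id = plots[pl], species = species_table$species[s],
        x_m = round(x, 2), y_m = round(y, 2),
        dbh_cm = round(pmax(5, dbh), 1), stringsAsFactors = FALSE)
    }
  }
  trees <- do.call(rbind, trees)
  ord <- order(trees$plot_id, trees$species, trees$x_m, trees$y_m)
  trees <- trees[ord, ]
  trees <- cbind(tree_id = sprintf("T%05d", seq_len(nrow(trees))), trees,
                 stringsAsFactors = FALSE)
  rownames(trees) <- NULL

  soil <- list()
  for (pl in plots) {
    pts <- soil_design_points(geometry)
    m <- config$means
    field <- function(mean_val) {
      tr <- smooth_trend(pts$x_m, pts$y_m, geometry, config$trend_sd)
      pmax(0, mean_val * exp(tr) * (1 + rnorm(nrow(pts), 0, config$noise_sd)))
    }
    no3_i <- field(m[["no3_i"]]); nh4_i <- field(m[["nh4_i"]])
    soil[[pl]] <- data.frame(
      plot_id = pl, x_m = pts$x_m, y_m = pts$y_m,
      no3_i = round(no3_i, 3), nh4_i = round(nh4_i, 3),
      no3_f = round(no3_i + field(config$mineralization[["no3"]]), 3),
      nh4_f = round(nh4_i + field(config$mineralization[["nh4"]]), 3),
      p = round(field(m[["p"]]), 3), k = round(field(m[["k"]]), 3),
      ca = round(field(m[["ca"]]), 3), mg = round(field(m[["mg"]]), 3),
      stringsAsFactors = FALSE)
  }
  soil <- do.call(rbind, soil)
  rownames(soil) <- NULL
  list(trees = trees, soil = soil)
}

#' True generative parameters for simulation
#'
#' Bundles the quantities that generate synthetic fruit observations:
#' per-species coefficients (drawn from the hyper-distribution unless
#' given), the hyper-mean and covariance, individual-effect precision,
#' crowding-kernel parameters, cut points, and the category scheme. The
#' default hyper-mean encodes the study's qualitative findings: strong
#' positive DBH effect, negative crowding effect, weak positive base-cation
#' effect.
#'
#' @param species character vector of species names.
#' @param covariate_set one of [covariate_sets()].
#' @param mu hyper-mean (default depends on the set).
#' @param Sigma hyper-covariance (default `0.3^2` identity).
#' @param beta per-species coefficient matrix (drawn MVN(mu, Sigma) if NULL).
#' @param tau individual-effect precision (default 4: sd 0.5).
#' @param alpha,nu crowding-kernel parameters, recycled per species.
#' @param gamma cut points (`K = 4` default `c(0, 1.8, 3.5)`).
#' @param scheme a [category_scheme()].
#' @param kernel,nci_scale crowding-index options (see [compute_nci()]).
#' @param seed seed for drawing `beta` when not supplied.
#' @return a `true_params` list.
#' @export
true_params <- function(species, covariate_set = "dbh_anci", mu = NULL,
                        Sigma = NULL, beta = NULL, tau = 4, alpha = 1,
                        nu = 1, gamma = c(0, 1.8, 3.5),
                        scheme = category_scheme(),
                        kernel = "as_printed", nci_scale = 100, seed = 1) {
  if (!covariate_set %in% covariate_sets()) stopf("unknown covariate set")
  J <- length(species)
  nm <- c("(Intercept)",
          if (set_has_dbh(covariate_set)) "dbh",
          if (set_has_soil(covariate_set)) c("nmin", "p", "sbc"),
          if (set_has_nci(covariate_set))
            (if (set_is_asymmetric(covariate_set)) "anci" else "nci"))
  p <- length(nm)
  if (is.null(mu)) {
    defaults <- c("(Intercept)" = -1, dbh = 1.5, nmin = 0.1, p = 0,
                  sbc = 0.3, nci = -1, anci = -1)
    mu <- unname(defaults[nm])
  }
  if (is.null(Sigma)) Sigma <- diag(0.3^2, p)
  if (is.null(beta)) {
    set.seed(derive_seed(seed, 2))
    beta <- MASS::mvrnorm(J, mu, Sigma)
    if (J == 1) beta <- matrix(beta, 1)
  }
  beta <- as.matrix(beta)
  dimnames(beta) <- list(species, nm)
  has_nci <- set_has_nci(covariate_set)
  structure(list(species = species, covariate_set = covariate_set,
                 beta = beta, mu = mu, Sigma = Sigma, tau = tau,
                 alpha = if (has_nci) rep_len(alpha, J),
                 nu = if (has_nci) rep_len(nu, J),
                 gamma = gamma, scheme = scheme, kernel = kernel,
                 nci_scale = nci_scale),
            class = "true_params")
}

#' Simulate ordinal fruit observations from known parameters
#'
#' Each tree's peak fruiting category is drawn from the cumulative-logit
#' model at the tree's covariates, true coefficients, individual effect
#' `eps_i ~ Normal(0, precision tau)`, and true kernel parameters. Under
#' the default `period_model = "peak"` the drawn category is observed in
#' one randomly chosen period (the species' peak fruiting window) and the
#' remaining periods show a category at or below it (truncated draw), so
#' that the maximum-category and any-fruit reductions follow the model
#' exactly. `period_model = "iid"` instead draws every period
#' independently from the same category distribution.
#'
#' @param trees,soil tables from [generate_forest()] (or real schemas).
#' @param truth a [true_params()] bundle.
#' @param n_periods number of observation periods (default 3).
#' @param seed integer seed.
#' @param period_model `"peak"` or `"iid"`.
#' @param latent_counts if TRUE, attach a counts table with a raw fruit
#'   count drawn log-uniformly within each observation's category bounds
#'   (top category capped at 10,000).
#' @param radius neighborhood radius, m.
#' @return fruit observations data frame (`tree_id`, `period`, `category`)
#'   with attributes `eps`, `eta`, `F` (per-tree max category), `design`,
#'   and optionally `counts`.
#' @export
simulate_fruit <- function(trees, soil, truth, n_periods = 3, seed = 1,
                           period_model = c("peak", "iid"),
                           latent_counts = FALSE, radius = 10) {
  period_model <- match.arg(period_model)
  if (n_periods < 1) stopf("n_periods must be >= 1")
  unknown <- setdiff(unique(trees$species), truth$species)
  if (length(unknown))
    stopf("tree species not in truth: %s", paste(unknown, collapse = ", "))
  design <- build_design(trees, soil, truth$covariate_set, radius = radius,
                         kernel = truth$kernel, nci_scale = truth$nci_scale)
  # map design species index (levels present in trees) to truth rows
  tr_idx <- match(design$species_levels, truth$species)
  K <- truth$scheme$K
  set.seed(derive_seed(seed, 3))
  n <- nrow(trees)
  eps <- rnorm(n, 0, 1 / sqrt(truth$tau))
  params <- fruit_params(beta = truth$beta[tr_idx, , drop = FALSE],
                         mu = truth$mu, Sigma = truth$Sigma, eps = eps,
                         tau = truth$tau,
                         alpha = truth$alpha[tr_idx], nu = truth$nu[tr_idx],
                         gamma = truth$gamma)
  eta <- linear_predictor(params, design)
  pi <- cumulative_category_probs(eta, truth$gamma, K)
  draw_cat <- function(p) {
    u <- runif(nrow(p))
    1L + rowSums(u > t(apply(p, 1, cumsum))[, -ncol(p), drop = FALSE])
  }
  obs <- matrix(1L, n, n_periods)
  if (period_model == "peak") {
    Fmax <- draw_cat(pi)
    peak <- sample.int(n_periods, n, replace = TRUE)
    for (pd in seq_len(n_periods)) {
      is_peak <- peak == pd
      obs[is_peak, pd] <- Fmax[is_peak]
      off <- which(!is_peak)
      if (length(off)) {
        ptr <- pi[off, , drop = FALSE]
        for (i in seq_along(off)) {
          Fi <- Fmax[off[i]]
          pr <- ptr[i, seq_len(Fi)]
          obs[off[i], pd] <- sample.int(Fi, 1, prob = pr)
        }
      }
    }
  } else {
    for (pd in seq_len(n_periods)) obs[, pd] <- draw_cat(pi)
    Fmax <- apply(obs, 1, max)
  }
  fruit <- data.frame(tree_id = rep(trees$tree_id, n_periods),
                      period = rep(seq_len(n_periods), each = n),
                      category = as.integer(obs),
                      stringsAsFactors = FALSE)
  if (latent_counts) {
    lo <- truth$scheme$lower
    up <- pmin(truth$scheme$upper, 10000)
    cc <- fruit$category
    cnt <- integer(nrow(fruit))
    pos <- cc > 1L
    cnt[pos] <- floor(exp(runif(sum(pos), log(lo[cc[pos]]),
                                log(up[cc[pos]] + 1))))
    cnt[pos] <- pmin(pmax(cnt[pos], lo[cc[pos]]), up[cc[pos]])
    attr(fruit, "counts") <- data.frame(tree_id = fruit$tree_id,
                                        period = fruit$period,
                                        category = cc, count = cnt,
                                        stringsAsFactors = FALSE)
  }
  attr(fruit, "eps") <- eps
  attr(fruit, "eta") <- eta
  attr(fruit, "F") <- Fmax
  attr(fruit, "design") <- design
  fruit
}

#' Read a simulation configuration from a structured text file
#'
#' Parses a YAML file with optional sections `geometry` (`width`,
#' `length`), `n_plots`, `n_periods`, `seed`, `species` (a list of records
#' with `species`, `abundance`, and optionally `dbh_meanlog`, `dbh_sdlog`,
#' `seed_mass_mg`), and `soil` (`trend_sd`, `noise_sd`, `means`,
#' `mineralization`). Omitted entries fall back to the package defaults.
#'
#' @param path YAML file.
#' @return named list of arguments for [simulate_dataset()]:
#'   `do.call(simulate_dataset, read_sim_config(path))`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the yaml package is required to read config files")
  cfg <- yaml::read_yaml(path)
  geo <- plot_geometry(width = cfg$geometry$width %||% 41,
                       length = cfg$geometry$length %||% 240)
  spt <- species_table_default()
  if (!is.null(cfg$species)) {
    user <- do.call(rbind, lapply(cfg$species, function(s) {
      stature <- s$stature %||% "sub"
      canopy <- stature == "canopy"
      data.frame(species = s$species, abundance = as.integer(s$abundance),
                 stature = stature,
                 seed_mass_mg = s$seed_mass_mg %||% NA_real_,
                 dbh_meanlog = s$dbh_meanlog %||% log(if (canopy) 16 else 9),
                 dbh_sdlog = s$dbh_sdlog %||% (if (canopy) 0.65 else 0.5),
                 stringsAsFactors = FALSE)
    }))
    spt <- user[names(spt)]
  }
  soil_args <- list()
  for (nm in c("trend_sd", "noise_sd"))
    if (!is.null(cfg$soil[[nm]])) soil_args[[nm]] <- cfg$soil[[nm]]
  if (!is.null(cfg$soil$means)) soil_args$means <- unlist(cfg$soil$means)
  if (!is.null(cfg$soil$mineralization))
    soil_args$mineralization <- unlist(cfg$soil$mineralization)
  list(geometry = geo, n_plots = cfg$n_plots %||% 5, species_table = spt,
       config = do.call(soil_config, soil_args),
       n_periods = cfg$n_periods %||% 3, seed = cfg$seed %||% 1)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_forest()] + [true_params()] +
#' [simulate_fruit()], returning a `fruit_data` bundle carrying the truth
#' and the seed in its metadata.
#'
#' @param geometry,n_plots,species_table,config forwarded to
#'   [generate_forest()].
#' @param truth a [true_params()] (defaults built from `species_table`).
#' @param n_periods,period_model,latent_counts forwarded to [simulate_fruit()].
#' @param seed integer seed used for all stages.
#' @param ... forwarded to [true_params()] when `truth` is NULL.
#' @return a `fruit_data` object with extra elements `truth` and `seed`.
#' @export
simulate_dataset <- function(geometry = plot_geometry(), n_plots = 5,
                             species_table = species_table_default(),
                             config = soil_config(), truth = NULL,
                             n_periods = 3, period_model = "peak",
                             latent_counts = FALSE, seed = 1, ...) {
  forest <- generate_forest(geometry, n_plots, species_table, config, seed)
  if (is.null(truth)) truth <- true_params(species_table$species, seed = seed, ...)
  fruit <- simulate_fruit(forest$trees, forest$soil, truth,
                          n_periods = n_periods, seed = seed,
                          period_model = period_model,
                          latent_counts = latent_counts)
  out <- fruit_data(forest$trees, forest$soil,
                    fruit[c("tree_id", "period", "category")],
                    counts = NULL, scheme = truth$scheme)
  out$truth <- truth
  out$seed <- seed
  out$sim <- attributes(fruit)[c("eps", "eta", "F", "counts")]
  out
}
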