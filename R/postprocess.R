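# Posterior-derived quantities: reproductive threshold sizes, the
# threshold-vs-maximum-size relationship, seed-mass regressions, and
# category-probability curves.

draws_beta <- function(fit, species, coefs) {
  draws <- as.matrix(fit)
  sapply(coefs, function(cf) {
    col <- paste0("beta[", species, ",", cf, "]")
    if (!col %in% colnames(draws)) stopf("parameter %s not in fit", col)
    draws[, col]
  })
}

#' Reproductive threshold size of a species
#'
#' The diameter at which the modeled probability of being reproductive is
#' 0.5. For each posterior draw of a binomial fit including DBH the
#' threshold solves `eta = 0` in closed form at reference covariates
#' (non-DBH covariates at their standardized zero, i.e. sample means;
#' individual effect 0): `dbh_z = -eta_ref / beta_dbh`, back-transformed
#' through the stored standardization moments. Draws with a non-positive
#' DBH coefficient leave the threshold undefined; they are excluded from
#' the summary and their fraction reported.
#'
#' @param fit a binomial `fruit_fit` whose covariate set includes DBH.
#' @param species species label.
#' @param dmax observed maximum DBH (cm) for the species (optional,
#'   carried through for the threshold-size regression).
#' @return list of class `threshold_estimate`: posterior `mean`, `sd`,
#'   quantiles, `draws` (cm), `excluded_fraction`, `dmax`.
#' @export
threshold_size <- function(fit, species, dmax = NA_real_) {
  model <- fit$model
  if (model$analysis != "binomial") stopf("threshold_size needs a binomial fit")
  if (!"dbh" %in% colnames(model$design$X))
    stopf("fitted covariate set has no DBH term")
  b <- draws_beta(fit, species, c("(Intercept)", "dbh"))
  ok <- b[, 2] > 0
  z <- -b[ok, 1] / b[ok, 2]
  mo <- model$design$moments$dbh
  dbh <- mo["mean"] + mo["sd"] * z
  structure(list(species = species,
                 mean = unname(mean(dbh)), sd = unname(sd(dbh)),
                 q2.5 = unname(quantile(dbh, 0.025)),
                 q97.5 = unname(quantile(dbh, 0.975)),
                 draws = unname(dbh),
                 excluded_fraction = mean(!ok), dmax = dmax),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: reproductive threshold %.1f cm (sd %.1f, 95%% CI %.1f-%.1f)%s\n",
    x$species, x$mean, x$sd, x$q2.5, x$q97.5,
    if (x$excluded_fraction > 0)
      sprintf(" [%.1f%% of draws excluded: beta_dbh <= 0]",
              100 * x$excluded_fraction) else ""))
  invisible(x)
}

#' Threshold size versus maximum size across species
#'
#' Ordinary least squares of `ln(D_thres)` on `ln(D_max)` across species,
#' plus the fit of the constrained line `ln(D_thres) = ln(D_max) - ln 2`
#' (threshold at half the maximum diameter), whose R-squared is computed
#' as `1 - SSR/SST` about the mean of `ln(D_thres)`.
#'
#' @param thresholds data frame with columns `species`, `dthres` (cm),
#'   `dmax` (cm), or a list of `threshold_estimate`s.
#' @return list with `fit` (lm), `slope`, `intercept`, `r_squared`,
#'   `r_squared_half_dmax`, `n`, and the data used.
#' @export
threshold_vs_dmax <- function(thresholds) {
  if (is.list(thresholds) && inherits(thresholds[[1]], "threshold_estimate"))
    thresholds <- data.frame(
      species = vapply(thresholds, `[[`, "", "species"),
      dthres = vapply(thresholds, `[[`, 0, "mean"),
      dmax = vapply(thresholds, `[[`, 0, "dmax"),
      stringsAsFactors = FALSE)
  bad <- !is.finite(thresholds$dthres) | thresholds$dthres <= 0
  if (any(bad)) {
    message("excluding ", sum(bad), " species with non-positive thresholds")
    thresholds <- thresholds[!bad, ]
  }
  if (nrow(thresholds) < 3) stopf("need >= 3 species")
  if (sd(thresholds$dmax) == 0) stopf("all species have identical dmax; regression undefined")
  lx <- log(thresholds$dmax)
  ly <- log(thresholds$dthres)
  fit <- lm(ly ~ lx)
  pred_half <- lx - log(2)
  sst <- sum((ly - mean(ly))^2)
  list(fit = fit, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       r_squared_half_dmax = 1 - sum((ly - pred_half)^2) / sst,
       n = nrow(thresholds), data = thresholds)
}

#' Seed-mass regressions
#'
#' Simple linear regressions of a per-species response (reproductive
#' threshold size, or a category's average probability) on literature dry
#' seed mass, reported with and without a configured exclusion list of
#' outlier species.
#'
#' @param response named numeric vector (names = species).
#' @param seed_mass named numeric vector of dry seed masses (mg); species
#'   with `NA` mass are dropped.
#' @param exclude species excluded in the restricted regression.
#' @return list with `all` and `excluded` elements, each holding `slope`,
#'   `p_value`, `r_squared`, `n`.
#' @export
seed_mass_regressions <- function(response, seed_mass,
                                  exclude = c("Dendropanax", "Goethalsia",
                                              "Laetia")) {
  common <- intersect(names(response), names(seed_mass)[is.finite(seed_mass)])
  one <- function(sp) {
    if (length(sp) < 3) stopf("fewer than 3 species with data after exclusion")
    f <- lm(response[sp] ~ seed_mass[sp])
    s <- summary(f)
    list(slope = unname(coef(f)[2]), p_value = s$coefficients[2, 4],
         r_squared = s$r.squared, n = length(sp))
  }
  list(all = one(common),
       excluded = one(setdiff(common, exclude)),
       species_used = common)
}

#' Average category probabilities over a species' size range
#'
#' For each posterior draw of an all-individual ordinal fit, category
#' probabilities are averaged over a uniform DBH grid spanning the
#' species' observed size range (other covariates at reference zero,
#' individual effect 0), then summarized over draws. The K averages sum
#' to 1.
#'
#' @param fit an ordinal `fruit_fit` including DBH.
#' @param species species label.
#' @param grid_n grid resolution.
#' @param max_draws posterior draws used (evenly thinned).
#' @return list with `mean` (length-K), `sd`, `dbh_range`.
#' @export
average_category_probabilities <- function(fit, species, grid_n = 41,
                                           max_draws = 1000) {
  model <- fit$model
  if (model$analysis != "ordinal") stopf("needs an ordinal fit")
  j <- match(species, model$design$species_levels)
  if (is.na(j)) stopf("species %s not in fit", species)
  rng <- range(model$design$dbh_cm[model$design$species == j])
  mo <- model$design$moments$dbh
  zgrid <- (seq(rng[1], rng[2], length.out = grid_n) - mo["mean"]) / mo["sd"]
  draws <- as.matrix(fit)
  idx <- unique(round(seq(1, nrow(draws), length.out = min(max_draws, nrow(draws)))))
  b <- draws_beta(fit, species, c("(Intercept)", "dbh"))[idx, , drop = FALSE]
  gcols <- if (model$K > 2) paste0("gamma[", seq(2, model$K - 1), "]")
  acc <- matrix(0, length(idx), model$K)
  for (r in seq_along(idx)) {
    eta <- b[r, 1] + b[r, 2] * zgrid
    gm <- if (model$K > 2) c(0, draws[idx[r], gcols]) else 0
    acc[r, ] <- colMeans(cumulative_category_probs(eta, gm, model$K))
  }
  list(mean = colMeans(acc), sd = apply(acc, 2, sd), dbh_range = rng,
       species = species)
}

#' Posterior prediction curves along DBH or the crowding index
#'
#' Posterior mean and central 95% band of each category probability
#' (ordinal fits) or of the probability of reproduction (binomial fits)
#' along a grid of the chosen axis, other covariates at reference zero and
#' individual effect 0. For `axis = "nci"` the (raw, unscaled) index value
#' is swept directly.
#'
#' @param fit a `fruit_fit`.
#' @param species species label.
#' @param axis `"dbh"` or `"nci"` (the latter also covers ANCI).
#' @param grid numeric axis grid (default: the species' observed DBH range,
#'   or 0..2 x the scale constant for the index).
#' @param max_draws posterior draws used.
#' @return data frame of class `prediction_curve`: `axis_value`,
#'   `category`, `mean`, `q2.5`, `q97.5`.
#' @export
prediction_curves <- function(fit, species, axis = c("dbh", "nci"),
                              grid = NULL, max_draws = 1000) {
  axis <- match.arg(axis)
  model <- fit$model
  d <- model$design
  j <- match(species, d$species_levels)
  if (is.na(j)) stopf("species %s not in fit", species)
  nci_name <- if (d$asymmetric) "anci" else "nci"
  if (axis == "dbh" && !"dbh" %in% colnames(d$X))
    stopf("DBH not in the fitted covariate set")
  if (axis == "nci" && !d$has_nci)
    stopf("crowding index not in the fitted covariate set")
  if (is.null(grid)) {
    grid <- if (axis == "dbh") {
      rng <- range(d$dbh_cm[d$species == j])
      seq(rng[1], rng[2], length.out = 50)
    } else seq(0, 2 * d$nci_scale, length.out = 50)
  }
  zgrid <- if (axis == "dbh") {
    mo <- d$moments$dbh
    (grid - mo["mean"]) / mo["sd"]
  } else grid / d$nci_scale
  slope_coef <- if (axis == "dbh") "dbh" else nci_name
  draws <- as.matrix(fit)
  idx <- unique(round(seq(1, nrow(draws), length.out = min(max_draws, nrow(draws)))))
  b <- draws_beta(fit, species, c("(Intercept)", slope_coef))[idx, , drop = FALSE]
  K <- if (model$analysis == "binomial") 1L else model$K
  gcols <- if (model$analysis == "ordinal" && model$K > 2)
    paste0("gamma[", seq(2, model$K - 1), "]")
  acc <- array(NA_real_, c(length(idx), length(grid), K))
  for (r in seq_along(idx)) {
    eta <- b[r, 1] + b[r, 2] * zgrid
    acc[r, , ] <- if (model$analysis == "binomial") plogis(eta)
    else cumulative_category_probs(
      eta, if (model$K > 2) c(0, draws[idx[r], gcols]) else 0, model$K)
  }
  out <- do.call(rbind, lapply(seq_len(K), function(k) {
    m <- acc[, , k, drop = FALSE]
    data.frame(axis = axis, axis_value = grid,
               category = if (model$analysis == "binomial") "reproductive"
                          else paste0("cat", k),
               mean = apply(m, 2, mean),
               q2.5 = apply(m, 2, quantile, 0.025),
               q97.5 = apply(m, 2, quantile, 0.975),
               stringsAsFactors = FALSE)
  }))
  attr(out, "species") <- species
  class(out) <- c("prediction_curve", "data.frame")
  out
}
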