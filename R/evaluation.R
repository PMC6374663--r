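# Model comparison (DIC, proper scoring rules) and effect classification.

# Rebuild a fruit_params-style state from a named draw vector (or vector of
# posterior means) plus individual effects.
state_from_vector <- function(model, v, eps = NULL) {
  d <- model$design
  cn <- coef_names(d)
  spn <- d$species_levels
  bn <- as.vector(t(outer(spn, cn, function(s, c) paste0("beta[", s, ",", c, "]"))))
  beta <- matrix(v[bn], model$J, model$p, byrow = TRUE,
                 dimnames = list(spn, cn))
  gamma <- NULL
  if (model$analysis == "ordinal")
    gamma <- if (model$K > 2)
      c(0, sort(v[paste0("gamma[", seq(2, model$K - 1), "]")])) else 0
  list(beta = beta,
       eps = eps,
       tau = if (model$include_ranef) unname(v["tau"]) else NULL,
       alpha = if (d$has_nci) unname(v[paste0("alpha[", spn, "]")]) else NULL,
       nu = if (d$has_nci) unname(v[paste0("nu[", spn, "]")]) else NULL,
       gamma = gamma)
}

# Total log-likelihood of a model at one state.
state_loglik <- function(model, st) {
  d <- model$design
  nci <- if (d$has_nci)
    pairs_nci(model$pairs, st$alpha, st$nu, d$kernel, model$n, d$nci_scale)
  else NULL
  eta <- rowSums(d$X * st$beta[d$species, seq_len(model$p_fix), drop = FALSE])
  if (d$has_nci) eta <- eta + st$beta[d$species, model$p] * nci
  if (!is.null(st$eps)) eta <- eta + st$eps
  br <- if (model$analysis == "ordinal")
    gamma_brackets(model$y, st$gamma, model$K)
  sum(model_ll(model, eta, br))
}

#' Deviance information criterion
#'
#' `Dbar` is the mean deviance over retained draws; `D(theta_bar)` is the
#' deviance at the posterior mean of every sampled quantity (species
#' coefficients, individual effects, kernel parameters, cut points - cut
#' points averaged then re-sorted); `pD = Dbar - D(theta_bar)` and
#' `DIC = Dbar + pD`. This is the conditional DIC, with the individual
#' random effects in focus.
#'
#' @param fit a `fruit_fit`.
#' @return list of class `fruit_dic` with `Dbar`, `D_at_mean`, `pD`, `DIC`.
#' @export
compute_dic <- function(fit) {
  dev <- unlist(fit$deviance)
  if (!all(is.finite(dev))) stopf("non-finite deviance draws; check the fit")
  Dbar <- mean(dev)
  v <- colMeans(as.matrix(fit))
  st <- state_from_vector(fit$model, v,
                          eps = if (fit$model$include_ranef) fit$eps_mean)
  D_at_mean <- -2 * state_loglik(fit$model, st)
  pD <- Dbar - D_at_mean
  structure(list(Dbar = Dbar, D_at_mean = D_at_mean, pD = pD,
                 DIC = Dbar + pD), class = "fruit_dic")
}

#' @export
print.fruit_dic <- function(x, ...) {
  cat(sprintf("DIC = %.1f (Dbar = %.1f, pD = %.1f)\n", x$DIC, x$Dbar, x$pD))
  invisible(x)
}

#' Proper scores of the posterior-mean predictive distribution
#'
#' Binomial models: Brier score and logarithmic score of the posterior-mean
#' predicted probability of reproduction against observed status. Ordinal
#' models: ranked probability score (RPS) of the posterior-mean predicted
#' category distribution against the observed category. Lower is better
#' for every score. The predictive averages over posterior draws of the
#' coefficients, kernel parameters and cut points, with individual effects
#' held at their posterior means.
#'
#' @param fit a `fruit_fit`.
#' @param max_draws number of (evenly thinned) posterior draws averaged.
#' @return named list of scores (`brier` and `log_score`, or `rps`).
#' @export
compute_scores <- function(fit, max_draws = 500) {
  model <- fit$model
  d <- model$design
  draws <- as.matrix(fit)
  idx <- unique(round(seq(1, nrow(draws), length.out = min(max_draws, nrow(draws)))))
  eps <- if (model$include_ranef) fit$eps_mean else NULL
  if (model$analysis == "binomial") {
    p_acc <- numeric(model$n)
    for (i in idx) {
      st <- state_from_vector(model, draws[i, ], eps)
      nci <- if (d$has_nci)
        pairs_nci(model$pairs, st$alpha, st$nu, d$kernel, model$n, d$nci_scale)
      eta <- rowSums(d$X * st$beta[d$species, seq_len(model$p_fix), drop = FALSE])
      if (d$has_nci) eta <- eta + st$beta[d$species, model$p] * nci
      if (!is.null(eps)) eta <- eta + eps
      p_acc <- p_acc + plogis(eta)
    }
    p_bar <- p_acc / length(idx)
    list(brier = mean((p_bar - model$y)^2),
         log_score = -mean(ifelse(model$y == 1L, log(p_bar), log1p(-p_bar))))
  } else {
    P_acc <- matrix(0, model$n, model$K)
    for (i in idx) {
      st <- state_from_vector(model, draws[i, ], eps)
      nci <- if (d$has_nci)
        pairs_nci(model$pairs, st$alpha, st$nu, d$kernel, model$n, d$nci_scale)
      eta <- rowSums(d$X * st$beta[d$species, seq_len(model$p_fix), drop = FALSE])
      if (d$has_nci) eta <- eta + st$beta[d$species, model$p] * nci
      if (!is.null(eps)) eta <- eta + eps
      P_acc <- P_acc + cumulative_category_probs(eta, st$gamma, model$K)
    }
    P_bar <- P_acc / length(idx)
    list(rps = ranked_probability_score(P_bar, model$y))
  }
}

#' Ranked probability score
#'
#' Mean over observations of the squared differences between forecast and
#' observed cumulative category distributions, divided by K - 1.
#'
#' @param P forecast probability matrix (n x K, rows sum to 1).
#' @param y observed categories in 1..K.
#' @return scalar score (0 for perfect forecasts).
#' @export
ranked_probability_score <- function(P, y) {
  K <- ncol(P)
  Q <- t(apply(P, 1, cumsum))
  O <- outer(y, seq_len(K), `<=`)
  mean(rowSums((Q[, -K, drop = FALSE] - O[, -K, drop = FALSE])^2) / (K - 1))
}

#' Classify effect strength from a posterior mean and SD
#'
#' Strong: the 95% credible interval (mean +- 2 SD) excludes zero.
#' Moderate: the 87% interval (mean +- 1.5 SD) excludes zero. Weak
#' otherwise. The sign is the sign of the posterior mean.
#'
#' @param mean,sd posterior mean(s) and SD(s), recycled.
#' @return data frame with `mean`, `sd`, `sign`, `strength`.
#' @examples
#' classify_effect(c(1, 1, 0.1), c(0.4, 0.6, 1))
#' @export
classify_effect <- function(mean, sd) {
  strength <- ifelse(abs(mean) > 2 * sd, "strong",
                     ifelse(abs(mean) > 1.5 * sd, "moderate", "weak"))
  data.frame(mean = mean, sd = sd,
             sign = ifelse(mean > 0, "+", ifelse(mean < 0, "-", "0")),
             strength = strength, stringsAsFactors = FALSE)
}

#' Effect-strength table for every species coefficient of a fit
#'
#' @param fit a `fruit_fit`.
#' @return data frame with species, covariate, posterior mean/sd, sign,
#'   strength.
#' @export
effect_table <- function(fit) {
  sm <- summarize_posterior(fit)
  bet <- sm[grepl("^beta\\[", sm$parameter), ]
  inner <- sub("^beta\\[(.*)\\]$", "\\1", bet$parameter)
  parts <- strsplit(inner, ",")
  cls <- classify_effect(bet$mean, bet$sd)
  data.frame(species = vapply(parts, `[`, "", 1),
             covariate = vapply(parts, `[`, "", 2),
             cls, stringsAsFactors = FALSE)
}

#' Compare fitted covariate sets by DIC and score
#'
#' Builds the comparison table for one analysis: DIC (Dbar, pD) and the
#' proper score for each fitted covariate set, with the minimum-DIC row
#' flagged. Fits must share the analysis type and the same data (checked
#' via a data fingerprint). DIC ties within `tie_tol` are broken toward
#' the set with fewer sampled parameters and flagged in the `tie` column.
#'
#' @param fits list of `fruit_fit` objects.
#' @param tie_tol absolute DIC difference treated as a tie.
#' @param scores include proper scores (slower; default TRUE).
#' @return data frame of class `model_comparison`.
#' @export
compare_models <- function(fits, tie_tol = 1e-8, scores = TRUE) {
  if (length(fits) < 2) stopf("need >= 2 fits to compare")
  fp <- lapply(fits, function(f) f$model$fingerprint)
  if (!all(vapply(fp, identical, TRUE, fp[[1]])))
    stopf("fits were made on different data subsets; refusing to compare")
  an <- vapply(fits, function(f) f$model$analysis, "")
  if (length(unique(an)) != 1) stopf("fits mix analysis types")
  rows <- lapply(fits, function(f) {
    dic <- compute_dic(f)
    sc <- if (scores) compute_scores(f) else NULL
    data.frame(label = f$model$label,
               covariate_set = f$model$design$covariate_set,
               n_params = ncol(f$samples[[1]]),
               Dbar = dic$Dbar, pD = dic$pD, DIC = dic$DIC,
               score = if (is.null(sc)) NA_real_ else sc[[1]],
               score_type = if (is.null(sc)) NA_character_ else names(sc)[1],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  near <- tab$DIC <= min(tab$DIC) + tie_tol
  best <- which(near)[order(tab$n_params[near])][1]
  tab$best <- seq_len(nrow(tab)) == best
  tab$tie <- near & sum(near) > 1
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (", x$score_type[1], " as score; * = lowest DIC)\n",
      sep = "")
  df <- data.frame(covariates = x$covariate_set,
                   DIC = sprintf("%.1f%s", x$DIC, ifelse(x$best, " *", "")),
                   pD = round(x$pD, 1), score = signif(x$score, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
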