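# MCMC fitting of the binomial and ordinal hierarchical models.
#
# Sampler: blocked adaptive random-walk Metropolis-within-Gibbs.
#   - individual effects eps_i: single-site random-walk updates, vectorized
#     (each eps_i enters only tree i's likelihood, so proposals are accepted
#     element-wise against per-tree likelihood differences);
#   - each species' coefficient vector beta_j: joint random-walk block,
#     all species proposed simultaneously and accepted per species;
#   - (log alpha_j, log nu_j): joint random-walk per species with the
#     crowding index recomputed from the stored neighbor lists;
#   - free cut points: joint random walk with ordering rejection;
#   - (mu, Sigma, tau): conjugate Gibbs draws.
# Proposal scales adapt by Robbins-Monro only during burn-in.

#' MCMC configuration
#'
#' The default is a desk-scale protocol (3 chains of 5,000 iterations,
#' 1,000 burn-in) suitable for tests and simulation studies; see
#' [paper_scale_config()] for the full-length protocol.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations (adaptation happens only here).
#' @param thin thinning interval; `(n_iter - n_burnin)` must be divisible
#'   by it.
#' @param seed integer seed; each chain derives its own sub-seed.
#' @param store_ranef if TRUE, store individual-effect draws (memory-heavy);
#'   their running means are always kept for DIC.
#' @param block_order update order of the parameter blocks.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 5000, n_burnin = 1000,
                        thin = 1, seed = 1, store_ranef = FALSE,
                        block_order = c("eps", "beta", "kernel", "gamma",
                                        "hyper")) {
  if (n_burnin >= n_iter) stopf("n_burnin must be < n_iter")
  if (thin < 1) stopf("thin must be >= 1")
  if ((n_iter - n_burnin) %% thin != 0)
    stopf("(n_iter - n_burnin) must be divisible by thin")
  if (!setequal(block_order, c("eps", "beta", "kernel", "gamma", "hyper")))
    stopf("block_order must be a permutation of the five update blocks")
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, seed = seed, store_ranef = store_ranef,
                 block_order = block_order), class = "mcmc_config")
}

#' Full-length chain protocol
#'
#' Three chains of 50,000 retained iterations after a 10,000-iteration
#' burn-in for the binomial analysis (150,000 posterior samples); three
#' chains of 100,000 iterations thinned to every tenth after the same
#' burn-in for the ordinal analyses (30,000 posterior samples).
#'
#' @param analysis `"binomial"` or `"ordinal"`.
#' @param seed integer seed.
#' @return an [mcmc_config()].
#' @export
paper_scale_config <- function(analysis = c("binomial", "ordinal"), seed = 1) {
  analysis <- match.arg(analysis)
  if (analysis == "binomial")
    mcmc_config(n_chains = 3, n_iter = 60000, n_burnin = 10000, thin = 1,
                seed = seed)
  else
    mcmc_config(n_chains = 3, n_iter = 110000, n_burnin = 10000, thin = 10,
                seed = seed)
}

#' Bundle a design and outcome into a fittable model
#'
#' @param design a [build_design()] result.
#' @param y outcome vector: 0/1 statuses (`analysis = "binomial"`) or
#'   ordinal categories 1..K (`analysis = "ordinal"`).
#' @param analysis `"binomial"` or `"ordinal"`.
#' @param K number of ordinal categories (ignored for binomial).
#' @param include_ranef include individual random effects.
#' @param hierarchical species coefficients share an MVN hyper-distribution;
#'   if FALSE each coefficient has an independent vague normal prior.
#' @param prior a [prior_config()].
#' @param label optional model label.
#' @return a `fruit_model` list.
#' @export
fruit_model <- function(design, y, analysis = c("binomial", "ordinal"),
                        K = 4L, include_ranef = TRUE, hierarchical = TRUE,
                        prior = prior_config(), label = NULL) {
  analysis <- match.arg(analysis)
  n <- nrow(design$X)
  if (length(y) != n) stopf("outcome length %d != %d trees", length(y), n)
  if (analysis == "binomial") {
    if (!all(y %in% c(0L, 1L))) stopf("binomial outcome must be 0/1")
    K <- 2L
  } else {
    if (!all(y %in% seq_len(K))) stopf("ordinal outcome must lie in 1..%d", K)
  }
  pairs <- NULL
  if (design$has_nci) {
    nb <- design$neighbors
    keep <- if (design$asymmetric) nb$larger else rep(TRUE, length(nb$focal))
    focal <- nb$focal[keep]
    ord <- order(focal)
    focal <- focal[ord]
    runs <- rle(focal)
    pairs <- list(focal = focal,
                  dbh = nb$dbh[keep][ord],
                  dist = nb$dist[keep][ord],
                  sp = design$species[focal],
                  ids = runs$values,                 # focal tree of each run
                  ends = cumsum(runs$lengths))       # run end positions
  }
  structure(list(design = design, y = as.integer(y), analysis = analysis,
                 K = as.integer(K), n = n, J = length(design$species_levels),
                 p_fix = ncol(design$X), p = ncol(design$X) + design$has_nci,
                 pairs = pairs, include_ranef = include_ranef,
                 hierarchical = hierarchical, prior = prior,
                 label = label %||% paste(analysis, design$covariate_set),
                 fingerprint = c(n = n, sum_y = sum(y),
                                 hash_y = sum(as.numeric(y) * seq_len(n)))),
            class = "fruit_model")
}

# Scaled crowding index for every tree from sorted pair arrays.
pairs_nci <- function(pairs, alpha, nu, kernel, n, scale) {
  w <- pairs$dbh^alpha[pairs$sp] *
    exp(if (kernel == "as_printed") -nu[pairs$sp] / pairs$dist
        else -nu[pairs$sp] * pairs$dist)
  out <- numeric(n)
  cs <- cumsum(w)[pairs$ends]
  out[pairs$ids] <- cs - c(0, cs[-length(cs)])
  out / scale
}

# Per-tree log-likelihood given eta (and ordinal brackets).
model_ll <- function(model, eta, br = NULL) {
  if (model$analysis == "binomial") bernoulli_ll(eta, model$y)
  else ordinal_ll_bracket(eta, br$up, br$lo)
}

# Initial values: independent logistic fits per species ignoring the
# hierarchy (fallback zeros), empirical cumulative-logit cut points.
initial_state <- function(model) {
  d <- model$design
  ybin <- if (model$analysis == "binomial") model$y else as.integer(model$y > 1L)
  nci0 <- if (d$has_nci)
    pairs_nci(model$pairs, rep(1, model$J), rep(1, model$J), d$kernel,
              model$n, d$nci_scale) else NULL
  beta <- matrix(0, model$J, model$p)
  for (j in seq_len(model$J)) {
    idx <- which(d$species == j)
    Xj <- d$X[idx, , drop = FALSE]
    if (d$has_nci) Xj <- cbind(Xj, nci0[idx])
    cf <- tryCatch(
      suppressWarnings(glm.fit(Xj, ybin[idx], family = binomial())$coefficients),
      error = function(e) rep(0, model$p))
    cf[!is.finite(cf)] <- 0
    beta[j, ] <- pmin(pmax(cf, -5), 5)
  }
  gamma <- NULL
  if (model$analysis == "ordinal" && model$K > 2) {
    cum <- cumsum(tabulate(model$y, model$K)) / model$n
    cum <- pmin(pmax(cum[-model$K], 0.02), 0.98)
    g <- qlogis(cum)
    g <- g - g[1]
    g <- cummax(g + seq_along(g) * 1e-3) # enforce strict ordering
    g[1] <- 0
    gamma <- g
  } else if (model$analysis == "ordinal") gamma <- 0
  list(beta = beta, gamma = gamma)
}

run_one_chain <- function(model, config, chain, init) {
  set.seed(derive_seed(config$seed, chain * 1000L))
  d <- model$design
  n <- model$n; J <- model$J; p <- model$p; p_fix <- model$p_fix
  sp <- d$species
  sp_count <- tabulate(sp, J)
  prior <- model$prior
  ordinal <- model$analysis == "ordinal"

  beta <- init$beta
  if (chain > 1) beta <- beta + matrix(rnorm(J * p, 0, 0.25), J, p)
  gamma <- init$gamma
  if (ordinal && model$K > 2 && chain > 1) {
    free <- gamma[-1] * exp(rnorm(model$K - 2, 0, 0.15))
    gamma <- c(0, sort(free))
  }
  eps <- numeric(n)
  tau <- 1
  mu <- colMeans(beta)
  Sigma <- diag(p); Sigma_inv <- diag(p)
  la <- numeric(J); lnv <- numeric(J)   # log alpha, log nu
  S0 <- prior$wishart_scale %||% diag(p)
  d0 <- p + prior$wishart_df_extra

  nci <- if (d$has_nci)
    pairs_nci(model$pairs, exp(la), exp(lnv), d$kernel, n, d$nci_scale)
  else numeric(n)
  Xb <- rowSums(d$X * beta[sp, seq_len(p_fix), drop = FALSE])
  bnci <- if (d$has_nci) beta[, p] else numeric(J)
  eta <- Xb + (if (d$has_nci) bnci[sp] * nci else 0) + eps
  br <- if (ordinal) gamma_brackets(model$y, gamma, model$K)
  ll <- model_ll(model, eta, br)
  if (!all(is.finite(ll))) {
    beta[] <- 0; mu[] <- 0
    Xb <- numeric(n); bnci[] <- 0; eta <- eps
    ll <- model_ll(model, eta, br)
    if (!all(is.finite(ll))) stopf("non-finite posterior at initialization")
  }

  # adaptive proposal log-scales
  ls_eps <- log(0.5); ls_beta <- rep(log(0.1), J)
  ls_kern <- rep(log(0.3), J); ls_gamma <- log(0.1)
  n_free <- if (ordinal) model$K - 2L else 0L

  n_keep <- (config$n_iter - config$n_burnin) %/% config$thin
  pn <- param_names(model)
  draws <- matrix(NA_real_, n_keep, length(pn), dimnames = list(NULL, pn))
  dev <- numeric(n_keep)
  eps_store <- if (config$store_ranef) matrix(NA_real_, n_keep, n)
  eps_sum <- numeric(n)
  keep_i <- 0L

  for (t in seq_len(config$n_iter)) {
    adapting <- t <= config$n_burnin
    step <- if (adapting) min(0.5, t^-0.6) else 0
    for (blk in config$block_order) {
      if (blk == "eps" && model$include_ranef) {
        prop <- eps + exp(ls_eps) * rnorm(n)
        eta_p <- eta + (prop - eps)
        ll_p <- model_ll(model, eta_p, br)
        dlp <- ll_p - ll - 0.5 * tau * (prop^2 - eps^2)
        dlp[is.na(dlp)] <- -Inf
        acc <- log(runif(n)) < dlp
        if (any(acc)) {
          eps[acc] <- prop[acc]; eta[acc] <- eta_p[acc]; ll[acc] <- ll_p[acc]
        }
        if (adapting) ls_eps <- ls_eps + step * (mean(acc) - 0.44)
      } else if (blk == "beta") {
        dB <- matrix(rnorm(J * p), J, p) * exp(ls_beta)
        deta <- rowSums(d$X * dB[sp, seq_len(p_fix), drop = FALSE])
        if (d$has_nci) deta <- deta + dB[sp, p] * nci
        eta_p <- eta + deta
        ll_p <- model_ll(model, eta_p, br)
        dll <- rowsum_by(ll_p - ll, sp, J)
        newB <- beta + dB
        if (model$hierarchical) {
          D0 <- sweep(beta, 2, mu); D1 <- sweep(newB, 2, mu)
          q0 <- rowSums((D0 %*% Sigma_inv) * D0)
          q1 <- rowSums((D1 %*% Sigma_inv) * D1)
          dpr <- -0.5 * (q1 - q0)
        } else {
          dpr <- -0.5 / prior$mu_sd^2 * (rowSums(newB^2) - rowSums(beta^2))
        }
        dlp <- dll + dpr
        dlp[is.na(dlp)] <- -Inf
        acc <- log(runif(J)) < dlp
        if (any(acc)) {
          beta[acc, ] <- newB[acc, , drop = FALSE]
          if (d$has_nci) bnci <- beta[, p]
          m <- acc[sp]
          eta[m] <- eta_p[m]; ll[m] <- ll_p[m]
        }
        if (adapting) ls_beta <- ls_beta + step * (as.numeric(acc) - 0.234)
      } else if (blk == "kernel" && d$has_nci) {
        # Joint move along the (beta_nci, alpha, nu) ridge: propose new
        # kernel parameters and rescale each species' crowding coefficient
        # so the mean crowding contribution c_j = beta_j,nci * mean(NCI_j)
        # is held fixed. This is a symmetric random walk in the
        # (c, log alpha, log nu) coordinates; the change of variables
        # contributes the Jacobian term log m - log m'.
        la_p <- la + exp(ls_kern) * rnorm(J)
        lnv_p <- lnv + exp(ls_kern) * rnorm(J)
        nci_p <- pairs_nci(model$pairs, exp(la_p), exp(lnv_p), d$kernel, n,
                           d$nci_scale)
        m0 <- rowsum_by(nci, sp, J) / sp_count
        m1 <- rowsum_by(nci_p, sp, J) / sp_count
        scl <- m0 / m1
        scl[!is.finite(scl) | m0 <= 0 | m1 <= 0] <- 1
        bnci_p <- bnci * scl
        eta_p <- eta + bnci_p[sp] * nci_p - bnci[sp] * nci
        ll_p <- model_ll(model, eta_p, br)
        dll <- rowsum_by(ll_p - ll, sp, J)
        # Gamma priors with log-scale Jacobians, plus the ridge Jacobian
        dpr <- prior$kernel_shape * (la_p - la) -
          prior$kernel_rate * (exp(la_p) - exp(la)) +
          prior$kernel_shape * (lnv_p - lnv) -
          prior$kernel_rate * (exp(lnv_p) - exp(lnv)) +
          ifelse(scl != 1, log(m0) - log(m1), 0)
        # prior change of the rescaled crowding coefficient
        newB <- beta
        newB[, p] <- bnci_p
        if (model$hierarchical) {
          D0 <- sweep(beta, 2, mu); D1 <- sweep(newB, 2, mu)
          dpr <- dpr - 0.5 * (rowSums((D1 %*% Sigma_inv) * D1) -
                                rowSums((D0 %*% Sigma_inv) * D0))
        } else {
          dpr <- dpr - 0.5 / prior$mu_sd^2 * (bnci_p^2 - bnci^2)
        }
        dlp <- dll + dpr
        dlp[is.na(dlp)] <- -Inf
        acc <- log(runif(J)) < dlp
        if (any(acc)) {
          la[acc] <- la_p[acc]; lnv[acc] <- lnv_p[acc]
          beta[acc, p] <- bnci_p[acc]
          bnci <- beta[, p]
          m <- acc[sp]
          nci[m] <- nci_p[m]; eta[m] <- eta_p[m]; ll[m] <- ll_p[m]
        }
        if (adapting) ls_kern <- ls_kern + step * (as.numeric(acc) - 0.234)
      } else if (blk == "gamma" && ordinal && n_free > 0L) {
        free_p <- gamma[-1] + exp(ls_gamma) * rnorm(n_free)
        ok <- !is.unsorted(c(0, free_p), strictly = TRUE)
        acc <- FALSE
        if (ok) {
          gm_p <- c(0, free_p)
          br_p <- gamma_brackets(model$y, gm_p, model$K)
          ll_p <- ordinal_ll_bracket(eta, br_p$up, br_p$lo)
          if (log(runif(1)) < sum(ll_p) - sum(ll)) {
            gamma <- gm_p; br <- br_p; ll <- ll_p; acc <- TRUE
          }
        }
        if (adapting) ls_gamma <- ls_gamma + step * (as.numeric(acc) - 0.234)
      } else if (blk == "hyper") {
        if (model$hierarchical) {
          prec <- J * Sigma_inv + diag(1 / prior$mu_sd^2, p)
          ch <- chol(prec)
          mu_mean <- backsolve(ch, forwardsolve(t(ch), Sigma_inv %*% colSums(beta)))
          mu <- as.vector(mu_mean + backsolve(ch, rnorm(p)))
          Dv <- sweep(beta, 2, mu)
          Spost <- S0 + crossprod(Dv)
          W <- rWishart(1, d0 + J, chol2inv(chol(Spost)))[, , 1]
          Sigma_inv <- W
          Sigma <- chol2inv(chol(W))
        }
        if (model$include_ranef)
          tau <- rgamma(1, prior$tau_shape + n / 2,
                        prior$tau_rate + sum(eps^2) / 2)
      }
    }
    if (!adapting && (t - config$n_burnin) %% config$thin == 0L) {
      keep_i <- keep_i + 1L
      draws[keep_i, ] <- flatten_state(model, beta, mu, Sigma, tau, la, lnv,
                                       gamma)
      dev[keep_i] <- -2 * sum(ll)
      eps_sum <- eps_sum + eps
      if (config$store_ranef) eps_store[keep_i, ] <- eps
    }
  }
  list(draws = draws, deviance = dev, eps_mean = eps_sum / max(1, keep_i),
       eps_draws = eps_store)
}

# Fast grouped sum of a numeric vector by integer group 1..J.
rowsum_by <- function(x, g, J) {
  out <- numeric(J)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

param_names <- function(model) {
  d <- model$design
  cn <- coef_names(d)
  spn <- d$species_levels
  nm <- as.vector(t(outer(spn, cn, function(s, c) paste0("beta[", s, ",", c, "]"))))
  if (model$hierarchical) {
    nm <- c(nm, paste0("mu[", cn, "]"))
    ut <- which(upper.tri(diag(model$p), diag = TRUE), arr.ind = TRUE)
    nm <- c(nm, paste0("Sigma[", ut[, 1], ",", ut[, 2], "]"))
  }
  if (model$include_ranef) nm <- c(nm, "tau")
  if (d$has_nci) nm <- c(nm, paste0("alpha[", spn, "]"), paste0("nu[", spn, "]"))
  if (model$analysis == "ordinal" && model$K > 2)
    nm <- c(nm, paste0("gamma[", seq(2, model$K - 1), "]"))
  nm
}

flatten_state <- function(model, beta, mu, Sigma, tau, la, lnv, gamma) {
  out <- as.vector(t(beta))
  if (model$hierarchical) out <- c(out, mu, Sigma[upper.tri(Sigma, diag = TRUE)])
  if (model$include_ranef) out <- c(out, tau)
  if (model$design$has_nci) out <- c(out, exp(la), exp(lnv))
  if (model$analysis == "ordinal" && model$K > 2) out <- c(out, gamma[-1])
  out
}

#' Fit a model by MCMC
#'
#' Runs the blocked adaptive Metropolis-within-Gibbs sampler for
#' `config$n_chains` chains and collects posterior draws and the deviance
#' trace. Reproducible: identical `(model, config)` give identical chains.
#'
#' @param model a [fruit_model()].
#' @param config an [mcmc_config()].
#' @return a `fruit_fit` object: per-chain draw matrices (named columns),
#'   deviance traces, posterior-mean individual effects, and the config.
#' @export
run_mcmc <- function(model, config = mcmc_config()) {
  stopifnot(inherits(model, "fruit_model"))
  init <- initial_state(model)
  chains <- lapply(seq_len(config$n_chains), function(ch)
    run_one_chain(model, config, ch, init))
  structure(list(
    samples = lapply(chains, `[[`, "draws"),
    deviance = lapply(chains, `[[`, "deviance"),
    eps_mean = Reduce(`+`, lapply(chains, `[[`, "eps_mean")) / length(chains),
    eps_draws = lapply(chains, `[[`, "eps_draws"),
    model = model, config = config), class = "fruit_fit")
}

#' @export
print.fruit_fit <- function(x, ...) {
  cat("fruit_fit:", x$model$label, "-", length(x$samples), "chains x",
      nrow(x$samples[[1]]), "retained draws,", ncol(x$samples[[1]]),
      "monitored parameters\n")
  invisible(x)
}

#' Combine chains into one draw matrix
#'
#' @param x a `fruit_fit`.
#' @param ... unused.
#' @return matrix of all retained draws (chains stacked), named columns.
#' @export
as.matrix.fruit_fit <- function(x, ...) do.call(rbind, x$samples)

#' Fit one of the three analyses to a dataset
#'
#' Applies the analysis' observation reduction, builds the design for the
#' requested covariate set, and runs the sampler:
#' * `"binom"`: binary reproductive status (any fruit in any period);
#' * `"amulti"`: maximum fruiting category over periods, all individuals
#'   (K = 4);
#' * `"rmulti"`: reproductive individuals only, original categories 2..K
#'   relabeled 1..K-1; species with fewer than `min_reproductive`
#'   reproductive individuals are excluded.
#'
#' @param data a `fruit_data` object.
#' @param analysis `"binom"`, `"amulti"`, or `"rmulti"`.
#' @param covariate_set one of [covariate_sets()].
#' @param config an [mcmc_config()].
#' @param radius,kernel,nci_scale crowding-index options.
#' @param min_reproductive rmulti species-inclusion threshold (default 2).
#' @param ... forwarded to [fruit_model()] (`include_ranef`,
#'   `hierarchical`, `prior`).
#' @return a `fruit_fit`.
#' @export
fit_fruit_model <- function(data, analysis = c("binom", "amulti", "rmulti"),
                            covariate_set = "dbh", config = mcmc_config(),
                            radius = 10, kernel = "as_printed",
                            nci_scale = 100, min_reproductive = 2, ...) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(data, "fruit_data"))
  red <- reduce_max_category(data$fruit)
  observed <- match(red$tree_id, data$trees$tree_id)
  unobserved <- setdiff(data$trees$tree_id, red$tree_id)
  if (length(unobserved))
    message(length(unobserved), " mapped trees never observed; excluded from fitting")
  trees_obs <- data$trees[observed, ]
  maxcat <- red$max_category
  design <- build_design(trees_obs, data$soil, covariate_set, radius = radius,
                         kernel = kernel, nci_scale = nci_scale)
  if (analysis == "binom") {
    model <- fruit_model(design, as.integer(maxcat > 1L), "binomial",
                         label = paste("binom", covariate_set), ...)
  } else if (analysis == "amulti") {
    model <- fruit_model(design, maxcat, "ordinal", K = data$scheme$K,
                         label = paste("amulti", covariate_set), ...)
  } else {
    rep_idx <- maxcat > 1L
    n_rep <- tapply(rep_idx, trees_obs$species, sum)
    keep_sp <- names(n_rep)[n_rep >= min_reproductive]
    keep <- which(rep_idx & trees_obs$species %in% keep_sp)
    if (!length(keep)) stopf("no reproductive individuals to fit")
    dropped <- setdiff(unique(trees_obs$species), keep_sp)
    if (length(dropped))
      message("rmulti: excluded species with < ", min_reproductive,
              " reproductive individuals: ", paste(dropped, collapse = ", "))
    model <- fruit_model(subset_design(design, keep),
                         maxcat[keep] - 1L, "ordinal", K = data$scheme$K - 1L,
                         label = paste("rmulti", covariate_set), ...)
  }
  run_mcmc(model, config)
}
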