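# Likelihoods and priors for the three analyses.
#
# Binomial analysis: reproductive status R_i ~ Bernoulli(pi_i),
#   logit(pi_i) = eta_i = x_i' beta_j + beta_[j,nci] * NCI_i / scale + eps_i.
# Ordinal analyses (K = 4 over all individuals; K = 3 over reproductive
# individuals with the zero class dropped): F_i ~ Multinomial(pi_i1..pi_iK),
#   pi_ik = Q_ik - Q_i,k-1, logit(Q_ik) = gamma_k - eta_i, Q_i0 = 0,
#   Q_iK = 1, cut points gamma_1 = 0 < gamma_2 < ... < gamma_{K-1}.
# Hierarchy: beta_j ~ MVN(mu, Sigma) across species; individual effects
#   eps_i ~ Normal(0, precision tau); crowding-kernel parameters
#   alpha_j, nu_j ~ Gamma(1, 1).

#' Model parameter bundle
#'
#' Collects every sampled quantity of one model state: the per-species
#' coefficient matrix `beta` (rows = species, columns named as in the
#' design, crowding coefficient last), hyper-mean `mu`, hyper-covariance
#' `Sigma`, individual effects `eps`, random-effect precision `tau`,
#' per-species kernel parameters `alpha` and `nu`, and ordinal cut points
#' `gamma` (first fixed at 0). Components not in the model may be `NULL`.
#'
#' @param beta numeric matrix (species x coefficients).
#' @param mu,Sigma hyper-mean vector and covariance matrix for rows of beta.
#' @param eps per-tree random effects (or NULL).
#' @param tau random-effect precision (> 0).
#' @param alpha,nu per-species crowding-kernel parameters (> 0), or NULL.
#' @param gamma cut points, `gamma[1] == 0`, strictly increasing; NULL for
#'   the binomial model.
#' @return a `fruit_params` list.
#' @export
fruit_params <- function(beta, mu = colMeans(beta),
                         Sigma = diag(ncol(beta)), eps = NULL, tau = 1,
                         alpha = NULL, nu = NULL, gamma = NULL) {
  beta <- as.matrix(beta)
  if (!is.null(gamma)) {
    if (gamma[1] != 0) stopf("first cut point must equal 0")
    if (is.unsorted(gamma, strictly = TRUE)) stopf("cut points must be strictly increasing")
  }
  if (tau <= 0) stopf("tau must be positive")
  if (!is.null(alpha) && any(alpha <= 0)) stopf("alpha must be positive")
  if (!is.null(nu) && any(nu <= 0)) stopf("nu must be positive")
  structure(list(beta = beta, mu = mu, Sigma = Sigma, eps = eps, tau = tau,
                 alpha = alpha, nu = nu, gamma = gamma),
            class = "fruit_params")
}

# Crowding index per tree under the current kernel parameters, already
# divided by the design's conditioning scale. Zero vector when absent.
design_nci <- function(design, params) {
  if (!design$has_nci) return(NULL)
  compute_nci(design$neighbors, params$alpha, params$nu,
              asymmetric = design$asymmetric, kernel = design$kernel,
              species = design$species) / design$nci_scale
}

#' Linear predictor for every tree
#'
#' `eta_i = x_i' beta_j(i) + beta_j(i),nci * NCI_i/scale + eps_i`, where the
#' crowding term is present only when the design's covariate set includes
#' NCI or ANCI, and the index is computed at the parameters' current
#' `alpha`, `nu`.
#'
#' @param params a [fruit_params()] bundle.
#' @param design a [build_design()] result.
#' @param nci optional precomputed scaled index vector (recomputed from
#'   `params` when NULL).
#' @return numeric vector eta, one value per tree.
#' @export
linear_predictor <- function(params, design, nci = NULL) {
  p_fix <- ncol(design$X)
  if (ncol(params$beta) != p_fix + design$has_nci)
    stopf("beta has %d columns; design requires %d", ncol(params$beta),
          p_fix + design$has_nci)
  eta <- rowSums(design$X * params$beta[design$species, seq_len(p_fix), drop = FALSE])
  if (design$has_nci) {
    if (is.null(nci)) nci <- design_nci(design, params)
    eta <- eta + params$beta[design$species, p_fix + 1L] * nci
  }
  if (!is.null(params$eps)) eta <- eta + params$eps
  eta
}

#' Category probabilities of the cumulative-logit model
#'
#' For latent score `eta` and cut points `gamma` (first anchored at 0),
#' the cumulative probability of being at or below category k is
#' `Q_k = logit^-1(gamma_k - eta)` for k < K, with `Q_K = 1`; class
#' probabilities are successive differences. Larger `eta` shifts mass to
#' higher categories.
#'
#' @param eta numeric vector of latent scores.
#' @param gamma cut points (length K-1, `gamma[1] == 0`, increasing).
#' @param K number of categories.
#' @return matrix `length(eta)` x `K` of probabilities; rows sum to 1.
#' @examples
#' cumulative_category_probs(0, c(0, 1, 2), 4)
#' @export
cumulative_category_probs <- function(eta, gamma, K = length(gamma) + 1L) {
  if (length(gamma) != K - 1L) stopf("need K-1 cut points")
  if (K > 2 && is.unsorted(gamma, strictly = TRUE))
    stopf("cut points must be strictly increasing")
  Q <- cbind(plogis(outer(eta, gamma, function(e, g) g - e)), 1)
  pi <- Q - cbind(0, Q[, -K, drop = FALSE])
  colnames(pi) <- paste0("cat", seq_len(K))
  pi
}

# Per-tree Bernoulli log-likelihood, stable in the tails.
bernoulli_ll <- function(eta, y) log_sigmoid(ifelse(y == 1L, eta, -eta))

# Per-tree ordinal log-likelihood from cut-point bracket values.
# up/lo are gamma_{F} and gamma_{F-1} per tree (+-Inf at the ends).
ordinal_ll_bracket <- function(eta, up, lo) {
  p <- plogis(up - eta) - plogis(lo - eta)
  log(pmax(p, 1e-300))
}

gamma_brackets <- function(y, gamma, K) {
  gfull <- c(-Inf, gamma, Inf)  # boundaries gamma_0 .. gamma_K
  list(up = gfull[y + 1L], lo = gfull[y])
}

#' Binomial (reproductive status) log-likelihood
#'
#' @param params a [fruit_params()] bundle.
#' @param statuses 0/1 vector, one per tree in the design.
#' @param design a [build_design()] result.
#' @return scalar log-likelihood.
#' @export
binomial_loglik <- function(params, statuses, design) {
  if (!all(statuses %in% c(0L, 1L))) stopf("statuses must be 0/1")
  sum(bernoulli_ll(linear_predictor(params, design), statuses))
}

#' Ordinal (fruit category) log-likelihood
#'
#' Supports K = 4 (all individuals) and K = 3 (reproductive individuals
#' only, original categories 2..4 relabeled 1..3).
#'
#' @param params a [fruit_params()] bundle including `gamma`.
#' @param F_values integer categories in 1..K, one per tree.
#' @param design a [build_design()] result.
#' @param K number of categories.
#' @return scalar log-likelihood.
#' @export
ordinal_loglik <- function(params, F_values, design, K = length(params$gamma) + 1L) {
  if (any(F_values < 1L | F_values > K)) stopf("categories must lie in 1..%d", K)
  if (length(params$gamma) != K - 1L) stopf("gamma must have K-1 elements")
  br <- gamma_brackets(F_values, params$gamma, K)
  sum(ordinal_ll_bracket(linear_predictor(params, design), br$up, br$lo))
}

#' Prior configuration
#'
#' Concrete versions of the model's vague priors: Normal(0, sd `mu_sd`) on
#' each element of the hyper-mean, inverse-Wishart(scale `wishart_scale`,
#' df `p + wishart_df_extra`) on the hyper-covariance, Gamma(`tau_shape`,
#' `tau_rate`) on the random-effect precision, Gamma(`kernel_shape`,
#' `kernel_rate`) on each crowding-kernel parameter, and a flat improper
#' prior on free cut points subject to ordering.
#'
#' @param mu_sd,wishart_df_extra,tau_shape,tau_rate,kernel_shape,kernel_rate
#'   scalars as described.
#' @param wishart_scale matrix or NULL for the identity.
#' @return a `prior_config` list.
#' @export
prior_config <- function(mu_sd = 100, wishart_df_extra = 2,
                         wishart_scale = NULL, tau_shape = 0.001,
                         tau_rate = 0.001, kernel_shape = 1, kernel_rate = 1) {
  structure(list(mu_sd = mu_sd, wishart_df_extra = wishart_df_extra,
                 wishart_scale = wishart_scale, tau_shape = tau_shape,
                 tau_rate = tau_rate, kernel_shape = kernel_shape,
                 kernel_rate = kernel_rate), class = "prior_config")
}

ldmvnorm <- function(x, mean, Sigma_inv, logdet) {
  d <- x - mean
  -0.5 * (length(x) * log(2 * pi) + logdet + sum(d * (Sigma_inv %*% d)))
}

#' Joint log-prior of a parameter bundle
#'
#' Sum of the MVN log-density of each species' coefficient row given
#' (`mu`, `Sigma`); Normal(0, precision `tau`) for each individual effect;
#' Gamma priors for `alpha`, `nu`, `tau`; Normal for `mu`; inverse-Wishart
#' for `Sigma`; flat (0) over ordered cut points. Returns `-Inf` outside
#' the support (tau <= 0, non-positive-definite Sigma, unordered gamma).
#'
#' @param params a [fruit_params()] bundle (may be an unvalidated list, so
#'   out-of-support states score `-Inf` rather than erroring).
#' @param prior a [prior_config()].
#' @param hierarchical if FALSE, rows of beta get independent
#'   Normal(0, `mu_sd`) priors and the (`mu`, `Sigma`) layer is absent.
#' @return scalar log-prior density.
#' @export
log_prior <- function(params, prior = prior_config(), hierarchical = TRUE) {
  if (!is.null(params$tau) && params$tau <= 0) return(-Inf)
  if (!is.null(params$gamma) &&
      (params$gamma[1] != 0 ||
       (length(params$gamma) > 1 && is.unsorted(params$gamma, strictly = TRUE))))
    return(-Inf)
  if (!is.null(params$alpha) && any(params$alpha <= 0)) return(-Inf)
  if (!is.null(params$nu) && any(params$nu <= 0)) return(-Inf)
  beta <- as.matrix(params$beta)
  p <- ncol(beta)
  lp <- 0
  if (hierarchical) {
    ch <- tryCatch(chol(params$Sigma), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Sigma_inv <- chol2inv(ch)
    for (j in seq_len(nrow(beta)))
      lp <- lp + ldmvnorm(beta[j, ], params$mu, Sigma_inv, logdet)
    lp <- lp + sum(stats::dnorm(params$mu, 0, prior$mu_sd, log = TRUE))
    # inverse-Wishart(S0, d0) with S0 = wishart_scale (identity default)
    S0 <- prior$wishart_scale %||% diag(p)
    d0 <- p + prior$wishart_df_extra
    lp <- lp - 0.5 * (d0 + p + 1) * logdet -
      0.5 * sum(diag(S0 %*% Sigma_inv))
  } else {
    lp <- lp + sum(stats::dnorm(beta, 0, prior$mu_sd, log = TRUE))
  }
  if (!is.null(params$eps)) {
    lp <- lp + sum(stats::dnorm(params$eps, 0, 1 / sqrt(params$tau), log = TRUE))
    lp <- lp + stats::dgamma(params$tau, prior$tau_shape, prior$tau_rate, log = TRUE)
  }
  if (!is.null(params$alpha))
    lp <- lp + sum(stats::dgamma(params$alpha, prior$kernel_shape,
                                 prior$kernel_rate, log = TRUE)) +
      sum(stats::dgamma(params$nu, prior$kernel_shape, prior$kernel_rate,
                        log = TRUE))
  lp
}
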