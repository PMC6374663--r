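test_that("cumulative category probabilities match inverse-logit arithmetic", {
  p <- cumulative_category_probs(0, c(0, 1, 2), 4)
  expect_equal(as.vector(p),
               c(0.5, plogis(1) - 0.5, plogis(2) - plogis(1), 1 - plogis(2)),
               tolerance = 1e-12)
  expect_equal(unname(p[1, 1]), 0.5)  # logit^-1(0) at the anchored first cut
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # extreme latent scores pile mass on the end categories
  expect_equal(as.vector(cumulative_category_probs(50, c(0, 1, 2), 4)),
               c(0, 0, 0, 1), tolerance = 1e-10)
  expect_equal(as.vector(cumulative_category_probs(-50, c(0, 1, 2), 4)),
               c(1, 0, 0, 0), tolerance = 1e-10)
  expect_error(cumulative_category_probs(0, c(0, 2, 1), 4), "increasing")
})

test_that("rows sum to one and ordering in eta is stochastic", {
  set.seed(1)
  for (rep in 1:50) {
    K <- sample(2:6, 1)
    gamma <- c(0, sort(runif(K - 2, 0.1, 4)))
    eta <- rnorm(20, 0, 3)
    p <- cumulative_category_probs(eta, gamma, K)
    expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-12)
    # larger eta => stochastically larger category
    p2 <- cumulative_category_probs(eta + 1, gamma, K)
    cum1 <- t(apply(p, 1, cumsum))
    cum2 <- t(apply(p2, 1, cumsum))
    expect_true(all(cum2 <= cum1 + 1e-12))
  }
})

test_that("linear predictor composes covariates, crowding and random effects", {
  tr <- tiny_trees(n = 20, seed = 5)
  tr$plot_id <- "p1"
  d <- build_design(tr, covariate_set = "dbh")
  sp_n <- length(d$species_levels)
  beta0 <- matrix(0, sp_n, 2)
  expect_equal(linear_predictor(fruit_params(beta0), d), rep(0, 20))
  # intercept-only effect: constant per species
  d0 <- build_design(tr, covariate_set = "intercept")
  b <- matrix(c(1.3, -0.4), sp_n, 1)[seq_len(sp_n), , drop = FALSE]
  eta <- linear_predictor(fruit_params(b), d0)
  expect_equal(eta, b[d0$species, 1])
  # hand-computed row with crowding term
  d2 <- build_design(tr, covariate_set = "dbh_anci")
  bb <- matrix(rnorm(sp_n * 3), sp_n, 3)
  pp <- fruit_params(bb, alpha = rep(0.8, sp_n), nu = rep(1.2, sp_n))
  eta2 <- linear_predictor(pp, d2)
  i <- 7
  j <- d2$species[i]
  nci_i <- compute_nci(d2$neighbors, pp$alpha, pp$nu, asymmetric = TRUE,
                       species = d2$species)[i] / d2$nci_scale
  expect_equal(eta2[i],
               as.numeric(bb[j, 1] + bb[j, 2] * d2$X[i, "dbh"] +
                            bb[j, 3] * nci_i),
               tolerance = 1e-12)
})

test_that("binomial log-likelihood equals the naive per-record product", {
  tr <- tiny_trees(n = 15, seed = 6)
  tr$plot_id <- "p1"
  d <- build_design(tr, covariate_set = "dbh")
  sp_n <- length(d$species_levels)
  set.seed(6)
  pars <- fruit_params(matrix(rnorm(sp_n * 2), sp_n, 2),
                       eps = rnorm(15, 0, 0.3))
  y <- rbinom(15, 1, 0.5)
  eta <- linear_predictor(pars, d)
  naive <- sum(log(ifelse(y == 1, plogis(eta), 1 - plogis(eta))))
  expect_equal(binomial_loglik(pars, y, d), naive, tolerance = 1e-10)
  # eta = 0 gives log(1/2) per record regardless of outcome
  p0 <- fruit_params(matrix(0, sp_n, 2))
  expect_equal(binomial_loglik(p0, y, d), 15 * log(0.5), tolerance = 1e-12)
})

test_that("two-category ordinal model reproduces the Bernoulli likelihood", {
  set.seed(7)
  for (rep in 1:20) {
    tr <- tiny_trees(n = 25, seed = rep)
    tr$plot_id <- "p1"
    d <- build_design(tr, covariate_set = "dbh")
    sp_n <- length(d$species_levels)
    pars <- fruit_params(matrix(rnorm(sp_n * 2), sp_n, 2), gamma = 0)
    y <- rbinom(25, 1, 0.5)
    expect_equal(ordinal_loglik(pars, y + 1L, d, K = 2),
                 binomial_loglik(pars, y, d), tolerance = 1e-10)
  }
})

test_that("ordinal likelihood is invariant to tree relabeling", {
  dat <- small_dataset(seed = 10, covariate_set = "dbh_nci")
  red <- reduce_max_category(dat$fruit)
  idx <- match(red$tree_id, dat$trees$tree_id)
  tr <- dat$trees[idx, ]
  d <- build_design(tr, dat$soil, "dbh_nci")
  sp_n <- length(d$species_levels)
  pars <- fruit_params(matrix(rnorm(sp_n * 3), sp_n, 3),
                       alpha = rep(1, sp_n), nu = rep(1, sp_n),
                       gamma = c(0, 1, 2))
  ll <- ordinal_loglik(pars, red$max_category, d, K = 4)
  perm <- sample(nrow(tr))
  d2 <- build_design(tr[perm, ], dat$soil, "dbh_nci")
  ll2 <- ordinal_loglik(pars, red$max_category[perm], d2, K = 4)
  expect_equal(ll, ll2, tolerance = 1e-8)
})

test_that("log-prior evaluates densities and respects the support", {
  b <- matrix(0, 2, 2)
  # unit-rate Gamma at alpha = nu = 1 contributes -2 for the pair
  base <- log_prior(fruit_params(b, alpha = c(1, 1), nu = c(1, 1)))
  no_kernel <- log_prior(fruit_params(b))
  expect_equal(base - no_kernel, 2 * (-2), tolerance = 1e-12)
  # beta at mu with identity Sigma: only normalizing constants remain
  p1 <- fruit_params(matrix(1:4 / 2, 2, 2), mu = c(0.5, 1.5),
                     Sigma = diag(2))
  p2 <- p1; p2$beta <- rbind(p1$mu, p1$mu)
  expect_gt(log_prior(p2), log_prior(p1))
  # out-of-support states
  bad_tau <- unclass(fruit_params(b)); bad_tau$tau <- -1
  expect_equal(log_prior(bad_tau), -Inf)
  bad_g <- unclass(fruit_params(b)); bad_g$gamma <- c(0, 2, 1)
  expect_equal(log_prior(bad_g), -Inf)
  bad_s <- unclass(fruit_params(b)); bad_s$Sigma <- matrix(c(1, 2, 2, 1), 2)
  expect_equal(log_prior(bad_s), -Inf)
})

test_that("log-prior responds to the configured hyper-prior scale", {
  b <- matrix(1, 2, 2)
  lp_wide <- log_prior(fruit_params(b), prior_config(mu_sd = 100),
                       hierarchical = FALSE)
  lp_narrow <- log_prior(fruit_params(b), prior_config(mu_sd = 1),
                         hierarchical = FALSE)
  expect_equal(lp_wide, sum(dnorm(b, 0, 100, log = TRUE)))
  expect_equal(lp_narrow, sum(dnorm(b, 0, 1, log = TRUE)))
})
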