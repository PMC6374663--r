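test_that("configs validate and count retained draws correctly", {
  cfg <- mcmc_config(n_chains = 2, n_iter = 1100, n_burnin = 100, thin = 10)
  expect_error(mcmc_config(n_iter = 100, n_burnin = 100), "n_burnin")
  expect_error(mcmc_config(n_iter = 106, n_burnin = 5, thin = 10),
               "divisible")
  expect_equal(paper_scale_config("binomial")$n_iter, 60000)
  expect_equal(paper_scale_config("ordinal")$thin, 10)
  dat <- small_dataset(seed = 2, n_species = 2, abundance = 25L)
  fit <- fit_fruit_model(dat, "binom", "dbh", config = cfg)
  # retained draws = chains x (iterations - burnin) / thin
  expect_equal(sapply(fit$samples, nrow), rep(100, 2))
  expect_equal(sapply(fit$deviance, length), rep(100, 2))
})

test_that("chains are reproducible for a fixed seed", {
  dat <- small_dataset(seed = 3, n_species = 2, abundance = 25L)
  cfg <- mcmc_config(n_chains = 2, n_iter = 600, n_burnin = 100, seed = 77)
  f1 <- fit_fruit_model(dat, "binom", "dbh", config = cfg)
  f2 <- fit_fruit_model(dat, "binom", "dbh", config = cfg)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- fit_fruit_model(dat, "binom", "dbh",
                        config = mcmc_config(n_chains = 2, n_iter = 600,
                                             n_burnin = 100, seed = 78))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("Gelman-Rubin diagnostic separates mixed from divergent chains", {
  set.seed(1)
  copy <- matrix(rnorm(1000), 500, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(gelman_rubin(list(copy, copy))), c(1, 1),
               tolerance = 1e-3)
  same <- lapply(1:2, function(i)
    matrix(rnorm(10000), 10000, 1, dimnames = list(NULL, "x")))
  expect_lt(gelman_rubin(same)["x"], 1.01)
  apart <- list(matrix(rnorm(500, 0), 500, 1, dimnames = list(NULL, "x")),
                matrix(rnorm(500, 10), 500, 1, dimnames = list(NULL, "x")))
  expect_gt(gelman_rubin(apart)["x"], 5)
  expect_error(gelman_rubin(apart[1]), "chains")
})

test_that("posterior summaries report both interval constructions", {
  const <- matrix(3.2, 200, 1, dimnames = list(NULL, "c"))
  sm <- summarize_posterior(list(const, const))
  expect_equal(sm$mean, 3.2)
  expect_equal(sm$sd, 0)
  expect_equal(sm$sd95_lo, 3.2)
  expect_equal(sm$q97.5, 3.2)
  set.seed(2)
  z <- lapply(1:2, function(i)
    matrix(rnorm(40000), ncol = 1, dimnames = list(NULL, "z")))
  smz <- summarize_posterior(z)
  expect_equal(smz$sd95_lo, -2, tolerance = 0.05)
  expect_equal(smz$sd95_hi, 2, tolerance = 0.05)
  expect_equal(smz$q2.5, qnorm(0.025), tolerance = 0.05)
  # skewed draws: the two constructions disagree and both are reported
  sk <- lapply(1:2, function(i)
    matrix(exp(rnorm(20000)), ncol = 1, dimnames = list(NULL, "s")))
  sms <- summarize_posterior(sk)
  expect_false(isTRUE(all.equal(sms$sd95_lo, sms$q2.5, tolerance = 0.01)))
  expect_error(summarize_posterior(list()), "empty")
})

test_that("generic random-walk sampler matches a conjugate posterior", {
  set.seed(5)
  x <- rnorm(30, 2, 1)
  # N(theta,1) likelihood with N(0,1) prior -> N(sum x/(n+1), 1/(n+1))
  draws <- rw_metropolis(function(th) -0.5 * th^2 - 0.5 * sum((x - th)^2),
                         init = 0, n_iter = 20000, n_burnin = 4000, seed = 8)
  expect_equal(mean(draws), sum(x) / 31, tolerance = 0.02)
  expect_equal(sd(draws), sqrt(1 / 31), tolerance = 0.02)
})

test_that("posterior is insensitive to the parameter-block update order", {
  dat <- small_dataset(seed = 6, n_species = 2, abundance = 40L)
  cfg1 <- mcmc_config(n_chains = 2, n_iter = 4000, n_burnin = 1000, seed = 5)
  cfg2 <- mcmc_config(n_chains = 2, n_iter = 4000, n_burnin = 1000, seed = 6,
                      block_order = c("hyper", "gamma", "kernel", "beta",
                                      "eps"))
  f1 <- fit_fruit_model(dat, "binom", "dbh", include_ranef = FALSE,
                        config = cfg1)
  f2 <- fit_fruit_model(dat, "binom", "dbh", include_ranef = FALSE,
                        config = cfg2)
  s1 <- summarize_posterior(f1); s2 <- summarize_posterior(f2)
  b <- grepl("^beta", s1$parameter)
  mc_se <- sqrt(s1$sd[b]^2 / s1$ess[b] + s2$sd[b]^2 / s2$ess[b])
  expect_true(all(abs(s1$mean[b] - s2$mean[b]) < 6 * mc_se + 0.1))
})

test_that("unobserved trees are excluded from fitting with a message", {
  dat <- small_dataset(seed = 9, n_species = 2, abundance = 30L)
  dat$fruit <- dat$fruit[dat$fruit$tree_id != dat$trees$tree_id[1], ]
  expect_message(
    fit <- fit_fruit_model(dat, "binom", "dbh",
                           config = mcmc_config(n_chains = 2, n_iter = 200,
                                                n_burnin = 100)),
    "never observed")
  expect_equal(fit$model$n, nrow(dat$trees) - 1L)
})

test_that("reproductive-only analysis relabels categories and excludes
          sparse species", {
  dat <- small_dataset(seed = 16, n_species = 3, abundance = 50L)
  # make one species (almost) never reproductive
  sp3 <- dat$trees$tree_id[dat$trees$species == dat$trees$species[
    match(species_table_default()$species[3], dat$trees$species)]]
  dat$fruit$category[dat$fruit$tree_id %in% sp3] <- 1L
  dat$fruit$category[dat$fruit$tree_id == sp3[1] & dat$fruit$period == 1] <- 3L
  expect_message(
    fit <- fit_fruit_model(dat, "rmulti", "dbh",
                           config = mcmc_config(n_chains = 2, n_iter = 400,
                                                n_burnin = 100, seed = 2)),
    "excluded species")
  expect_equal(fit$model$K, 3L)
  expect_true(all(fit$model$y %in% 1:3))
  expect_equal(length(fit$model$design$species_levels), 2)
  # relabeled outcome equals original max category minus one
  red <- reduce_max_category(dat$fruit)
  kept <- match(fit$model$design$tree_id, red$tree_id)
  expect_equal(fit$model$y, red$max_category[kept] - 1L)
  # only one free cut point for K = 3
  expect_true("gamma[2]" %in% colnames(fit$samples[[1]]))
  expect_false("gamma[3]" %in% colnames(fit$samples[[1]]))
})

test_that("simulation-based calibration ranks are uniform at small scale", {
  # Draw coefficients from a narrowed prior, simulate statuses, fit with the
  # same prior, and rank the truth among posterior draws. With a correct
  # sampler the ranks are uniform; checked with a chi-squared test.
  set.seed(31)
  n <- 40
  tr <- tiny_trees(n = n, seed = 31, species = "One")
  tr$plot_id <- "p1"
  des <- build_design(tr, covariate_set = "dbh")
  pr <- prior_config(mu_sd = 1.5)
  n_rep <- 24
  bins <- 4
  ranks <- matrix(NA_real_, n_rep, 2)
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    b_true <- rnorm(2, 0, 1.5)
    y <- rbinom(n, 1, plogis(b_true[1] + b_true[2] * des$X[, "dbh"]))
    model <- fruit_model(des, y, "binomial", include_ranef = FALSE,
                         hierarchical = FALSE, prior = pr)
    fit <- run_mcmc(model, mcmc_config(n_chains = 2, n_iter = 1600,
                                       n_burnin = 600, thin = 10,
                                       seed = 2000 + r))
    draws <- as.matrix(fit)
    ranks[r, ] <- sapply(1:2, function(k) mean(draws[, k] < b_true[k]))
  }
  for (k in 1:2) {
    counts <- tabulate(pmin(floor(ranks[, k] * bins) + 1, bins), bins)
    pval <- suppressWarnings(chisq.test(counts)$p.value)
    expect_gt(pval, 0.001)
  }
})
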