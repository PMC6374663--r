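make_binom_fit <- function(seed = 21, n_species = 2, abundance = 80L,
                           beta = NULL) {
  spt <- species_table_default()[seq_len(n_species), ]
  spt$abundance <- rep(abundance, n_species)
  truth <- true_params(spt$species, "dbh", beta = beta, seed = seed)
  dat <- simulate_dataset(n_plots = 1, species_table = spt, truth = truth,
                          seed = seed)
  list(dat = dat, truth = truth,
       fit = fit_fruit_model(dat, "binom", "dbh",
                             config = mcmc_config(n_chains = 2, n_iter = 2000,
                                                  n_burnin = 500, seed = seed)))
}

test_that("threshold solves eta = 0 in closed form and back-transforms", {
  # beta = (-2, 1), moments mean 20 / sd 10 -> dbh_z = 2 -> 40 cm
  z <- -(-2) / 1
  expect_equal(20 + 10 * z, 40)
  fb <- make_binom_fit(seed = 21)
  fit <- fb$fit
  thr <- threshold_size(fit, fit$model$design$species_levels[1])
  expect_s3_class(thr, "threshold_estimate")
  expect_gt(thr$mean, 0)
  # manual recomputation from the draws
  b <- as.matrix(fit)
  sp <- fit$model$design$species_levels[1]
  b0 <- b[, paste0("beta[", sp, ",(Intercept)]")]
  b1 <- b[, paste0("beta[", sp, ",dbh]")]
  mo <- fit$model$design$moments$dbh
  manual <- unname(mo["mean"] - mo["sd"] * b0[b1 > 0] / b1[b1 > 0])
  expect_equal(thr$mean, mean(manual), tolerance = 1e-12)
  expect_equal(thr$excluded_fraction, mean(b1 <= 0))
  # intercept 0 draw solves at the sample-mean DBH
  expect_equal(unname(mo["mean"] - mo["sd"] * 0 / 1.5), unname(mo["mean"]))
  expect_error(threshold_size(fit, "Nonesuch"), "not in fit")
})

test_that("closed-form threshold agrees with bisection of the mean curve", {
  fb <- make_binom_fit(seed = 22)
  fit <- fb$fit
  sp <- fit$model$design$species_levels[2]
  b <- as.matrix(fit)
  b0 <- mean(b[, paste0("beta[", sp, ",(Intercept)]")])
  b1 <- mean(b[, paste0("beta[", sp, ",dbh]")])
  mo <- fit$model$design$moments$dbh
  closed <- unname(mo["mean"] - mo["sd"] * b0 / b1)
  bisect <- uniroot(function(d) plogis(b0 + b1 * (d - mo["mean"]) / mo["sd"]) - 0.5,
                    interval = c(-1000, 5000), tol = 1e-10)$root
  expect_equal(closed, bisect, tolerance = 1e-8)
})

test_that("threshold-vs-maximum regression recovers exact and noisy laws", {
  # exact half-of-maximum law: constrained R^2 = 1, slope 1
  dmax <- c(20, 40, 60, 90, 120)
  exact <- data.frame(species = letters[1:5], dthres = dmax / 2, dmax = dmax)
  r <- suppressWarnings(threshold_vs_dmax(exact))  # exact fit is intended
  expect_equal(r$r_squared_half_dmax, 1, tolerance = 1e-12)
  expect_equal(r$slope, 1, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  # identical maxima: regression undefined
  same <- data.frame(species = letters[1:4], dthres = c(10, 12, 14, 16),
                     dmax = 50)
  expect_error(threshold_vs_dmax(same), "identical")
  # lognormal noise around the half-maximum law: slope near 1
  set.seed(9)
  dmax16 <- exp(runif(16, log(15), log(150)))
  noisy <- data.frame(species = paste0("s", 1:16),
                      dthres = dmax16 / 2 * exp(rnorm(16, 0, 0.2)),
                      dmax = dmax16)
  rn <- threshold_vs_dmax(noisy)
  se <- summary(rn$fit)$coefficients[2, 2]
  expect_lt(abs(rn$slope - 1), 3 * se)
  expect_gt(rn$r_squared_half_dmax, 0.7)
})

test_that("seed-mass regressions honor exclusions and recover known slopes", {
  set.seed(10)
  sm <- c(Capparis = 721, Casearia = 1.32, Coussarea = 128, Euterpe = 370,
          Goethalsia = 4.3, Iriartea = 3419, Laetia = 5.2,
          Pentaclethra = 3697, Welfia = 1729)
  resp <- 10 + 0.004 * sm + rnorm(length(sm), 0, 0.5)
  names(resp) <- names(sm)
  r <- seed_mass_regressions(resp, sm)
  expect_equal(r$all$n, 9)
  expect_equal(r$excluded$n, 7)  # Goethalsia and Laetia dropped
  se <- 0.004 / 5  # generous bound; slope is recovered much closer than this
  expect_lt(abs(r$all$slope - 0.004), se)
  expect_gt(r$all$r_squared, 0.9)
  # perfectly collinear points
  r2 <- suppressWarnings(
    seed_mass_regressions(setNames(2 * sm + 1, names(sm)), sm,
                          exclude = character()))
  expect_equal(r2$all$r_squared, 1, tolerance = 1e-12)
  expect_error(seed_mass_regressions(resp[1:3], sm[1:3],
                                     exclude = names(sm)[1:2]),
               "fewer than 3")
})

test_that("average category probabilities normalize and track size range", {
  spt <- species_table_default()[1:2, ]
  spt$abundance <- c(80L, 80L)
  truth <- true_params(spt$species, "dbh", seed = 23)
  dat <- simulate_dataset(n_plots = 1, species_table = spt, truth = truth,
                          seed = 23)
  fit <- fit_fruit_model(dat, "amulti", "dbh",
                         config = mcmc_config(n_chains = 2, n_iter = 1500,
                                              n_burnin = 500, seed = 23))
  sp <- fit$model$design$species_levels[1]
  av <- average_category_probabilities(fit, sp)
  expect_equal(sum(av$mean), 1, tolerance = 1e-10)
  expect_length(av$mean, 4)
  expect_error(average_category_probabilities(fit, "Nonesuch"), "not in fit")
})

test_that("prediction curves normalize, band their means, and rise with DBH", {
  fb <- make_binom_fit(seed = 24)
  fit <- fb$fit
  sp <- fit$model$design$species_levels[1]
  cv <- prediction_curves(fit, sp, axis = "dbh")
  expect_true(all(cv$q2.5 <= cv$mean + 1e-12 & cv$mean <= cv$q97.5 + 1e-12))
  # positive true DBH effect: posterior-mean curve increases
  expect_gt(cor(cv$axis_value, cv$mean), 0.9)
  expect_error(prediction_curves(fit, sp, axis = "nci"), "not in the fitted")
  # ordinal curves: stacked categories span the simplex at every grid point
  spt <- species_table_default()[1:2, ]
  spt$abundance <- c(60L, 60L)
  truth <- true_params(spt$species, "dbh", seed = 25)
  dat <- simulate_dataset(n_plots = 1, species_table = spt, truth = truth,
                          seed = 25)
  fo <- fit_fruit_model(dat, "amulti", "dbh",
                        config = mcmc_config(n_chains = 2, n_iter = 1000,
                                             n_burnin = 200, seed = 25))
  cvo <- prediction_curves(fo, fo$model$design$species_levels[1])
  sums <- tapply(cvo$mean, cvo$axis_value, sum)
  expect_true(all(abs(sums - 1) < 1e-10))
})
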