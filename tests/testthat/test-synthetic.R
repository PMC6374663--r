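test_that("generated stems respect plot bounds and the census threshold", {
  spt <- species_table_default()[1:2, ]
  spt$abundance <- c(50L, 50L)
  f <- generate_forest(n_plots = 1, species_table = spt, seed = 1)
  expect_equal(nrow(f$trees), 100)
  expect_true(all(f$trees$x_m >= 0 & f$trees$x_m <= 41))
  expect_true(all(f$trees$y_m >= 0 & f$trees$y_m <= 240))
  expect_true(all(f$trees$dbh_cm >= 5))
  # clustered placement keeps the same invariants
  fc <- generate_forest(n_plots = 1, species_table = spt, seed = 1,
                        clustered = TRUE)
  expect_true(all(fc$trees$x_m >= 0 & fc$trees$x_m <= 41))
  expect_true(all(fc$trees$y_m >= 0 & fc$trees$y_m <= 240))
  expect_error(generate_forest(plot_geometry(width = -1)), "positive")
  spt$abundance[1] <- 0L
  expect_error(generate_forest(species_table = spt), "abundance")
})

test_that("soil design has the transect plus 10-m lattice layout", {
  f <- generate_forest(n_plots = 1, species_table = species_table_default(),
                       seed = 2)
  # independently enumerated for a 41 x 240 plot:
  # 200 meter-spaced transect composites + a 10-m lattice of
  # (floor((41-5)/10)+1) x (floor((240-5)/10)+1) = 4 x 24 points
  expect_equal(nrow(f$soil), 200 + 4 * 24)
  transect <- f$soil[f$soil$x_m == 20.5, ]
  expect_equal(nrow(transect), 200)
  expect_equal(sort(unique(diff(sort(transect$y_m)))), 1)
  lattice <- f$soil[f$soil$x_m != 20.5, ]
  expect_true(all(diff(sort(unique(lattice$x_m))) == 10))
  expect_true(all(diff(sort(unique(lattice$y_m))) == 10))
  expect_true(all(f$soil[, 4:11] >= 0))
})

test_that("identical configuration and seed reproduce identical tables", {
  a <- generate_forest(n_plots = 2, seed = 42)
  b <- generate_forest(n_plots = 2, seed = 42)
  expect_identical(a, b)
  d1 <- small_dataset(seed = 5)
  d2 <- small_dataset(seed = 5)
  expect_identical(d1$trees, d2$trees)
  expect_identical(d1$fruit, d2$fruit)
  d3 <- small_dataset(seed = 6)
  expect_false(identical(d1$fruit, d3$fruit))
})

test_that("extreme coefficients force the end categories", {
  spt <- species_table_default()[1:2, ]
  spt$abundance <- c(30L, 30L)
  f <- generate_forest(n_plots = 1, species_table = spt, seed = 3)
  lo <- true_params(spt$species, "dbh",
                    beta = matrix(c(-50, -50, 0, 0), 2, 2), tau = 1e6)
  fr_lo <- simulate_fruit(f$trees, f$soil, lo, seed = 3)
  expect_true(all(fr_lo$category == 1L))
  hi <- true_params(spt$species, "dbh",
                    beta = matrix(c(50, 50, 0, 0), 2, 2), tau = 1e6)
  fr_hi <- simulate_fruit(f$trees, f$soil, hi, seed = 3)
  expect_true(all(attr(fr_hi, "F") == 4L))
  # unknown species rejected
  bad <- f$trees
  bad$species[1] <- "Nonesuch"
  expect_error(simulate_fruit(bad, f$soil, lo, seed = 1), "Nonesuch")
})

test_that("category frequencies converge to the analytic probabilities", {
  spt <- species_table_default()[1:4, ]
  spt$abundance <- rep(2500L, 4)
  truth <- true_params(spt$species, "dbh", seed = 7)
  f <- generate_forest(n_plots = 1, species_table = spt, seed = 7)
  fr <- simulate_fruit(f$trees, f$soil, truth, seed = 7)
  d <- attr(fr, "design")
  tr_idx <- match(d$species_levels, truth$species)
  pars <- fruit_params(truth$beta[tr_idx, ], eps = attr(fr, "eps"),
                       gamma = truth$gamma)
  pi <- cumulative_category_probs(linear_predictor(pars, d), truth$gamma, 4)
  expected <- colMeans(pi)
  emp <- tabulate(attr(fr, "F"), 4) / nrow(f$trees)
  se <- sqrt(colSums(pi * (1 - pi))) / nrow(f$trees)
  expect_true(all(abs(emp - expected) <= 4 * se + 1e-8))
})

test_that("latent counts fall inside their category bounds", {
  dat_fr <- simulate_fruit_counts_fixture()
  sc <- category_scheme()
  cnt <- attr(dat_fr, "counts")
  expect_equal(assign_category(cnt$count, sc), cnt$category)
  expect_true(all(cnt$count[cnt$category == 4] <= 10000))
  expect_true(all(cnt$count[cnt$category == 1] == 0))
})

test_that("a YAML configuration drives the generator reproducibly", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "geometry: {width: 41, length: 120}",
    "n_plots: 1",
    "seed: 5",
    "species:",
    "  - {species: Casearia, abundance: 30}",
    "  - {species: Welfia, abundance: 40, stature: canopy}",
    "soil: {trend_sd: 0.2, noise_sd: 0.05}"), path)
  args <- read_sim_config(path)
  expect_equal(args$geometry$length, 120)
  expect_equal(args$species_table$abundance, c(30L, 40L))
  expect_equal(args$config$trend_sd, 0.2)
  d1 <- do.call(simulate_dataset, args)
  d2 <- do.call(simulate_dataset, args)
  expect_identical(d1$trees, d2$trees)
  expect_equal(nrow(d1$trees), 70)
  expect_true(all(d1$trees$y_m <= 120))
})

test_that("per-period observations never exceed the peak category", {
  dat <- small_dataset(seed = 11)
  per_tree_max <- reduce_max_category(dat$fruit)
  expect_equal(sort(per_tree_max$tree_id), sort(dat$trees$tree_id))
  m <- merge(dat$fruit, per_tree_max)
  expect_true(all(m$category <= m$max_category))
  # every tree observed in every period
  expect_equal(nrow(dat$fruit), 3 * nrow(dat$trees))
})
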