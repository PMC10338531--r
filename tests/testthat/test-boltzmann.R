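# Boltzmann weighting, composites, hybrid composition and cost accounting.

test_that("Boltzmann weights match closed forms and are shift invariant", {
  expect_equal(boltzmann_weights(rep(2.5, 7)), rep(1 / 7, 7))
  expect_equal(boltzmann_weights(5), 1)

  kT <- 0.0019872041 * 298.15
  w <- boltzmann_weights(c(0, kT * log(2)))
  expect_equal(w, c(2 / 3, 1 / 3), tolerance = 1e-12)

  set.seed(12)
  for (i in 1:50) {
    e <- rnorm(6, sd = 3)
    shift <- runif(1, -100, 100)
    expect_equal(boltzmann_weights(e + shift), boltzmann_weights(e),
                 tolerance = 1e-12)
    expect_equal(sum(boltzmann_weights(e)), 1, tolerance = 1e-12)
  }
  expect_error(boltzmann_weights(c(0, 1), temperature = 0), "positive")
})

test_that("composite spectra are weighted sums, permutation invariant", {
  g <- small_grid()
  sp <- lapply(1:3, function(i) vcd_spectrum(g, rnorm(g$points)))
  w <- c(0.5, 0.3, 0.2)
  comp <- composite_spectrum(sp, w)
  brute <- 0.5 * sp[[1]]$values + 0.3 * sp[[2]]$values + 0.2 * sp[[3]]$values
  expect_equal(comp$values, brute, tolerance = 1e-12)

  perm <- c(3, 1, 2)
  expect_equal(composite_spectrum(sp[perm], w[perm])$values, comp$values,
               tolerance = 1e-12)

  expect_equal(composite_spectrum(sp[1], 1)$values, sp[[1]]$values)
  s <- sp[[1]]
  expect_equal(composite_spectrum(list(s, mirror_spectrum(s)),
                                  c(0.5, 0.5))$values,
               numeric(g$points))
  expect_error(composite_spectrum(sp, c(0.5, 0.3, 0.1)), "sum to 1")
})

test_that("cost accounting reproduces the reference workload arithmetic", {
  r <- cost_report(100, 80, 1, 0)
  expect_equal(r$speedup, 1.25)
  expect_equal(r$savings, 20)
  expect_equal(cost_report(50, 50, 2, 0)$speedup, 1)
  # replay of the published compound-1a workload: classical 7140 h,
  # reference part of the aided workflow 5707 h, model build 7 h
  r1a <- cost_report(7140, 5707, 1, 7)
  expect_equal(r1a$classical_cost, 7140)
  expect_equal(r1a$aided_cost, 5714)
  expect_equal(r1a$savings, 1426)
  expect_error(cost_report(10, 11, 1, 0), "n_reference")
})

test_that("hybrid composite at fraction 1 is identical to the all-reference composite", {
  recs <- linear_map_records(20)
  for (i in seq_along(recs)) recs[[i]]$energy <- runif(1, 0, 3)
  m <- train_fnn(recs[1:16], recs[17:20],
                 trial_config(hidden_layers = 1, neurons_per_layer = 50),
                 seed = 2, control = fnn_control(max_epochs = 5))
  hc <- hybrid_composite(recs, m, dft_fraction = 1)
  w <- boltzmann_weights(vapply(recs, `[[`, numeric(1), "energy"))
  full <- composite_spectrum(lapply(recs, `[[`, "spectrum"), w)
  expect_identical(hc$spectrum$values, full$values)
  expect_equal(hc$theta, 1.0)
  expect_true(all(hc$report$source == "reference"))
})

test_that("hybrid composite selects by energy, predicts the rest and reports sources", {
  recs <- linear_map_records(40)
  for (i in seq_along(recs)) recs[[i]]$energy <- (i - 1) * 0.2
  m <- train_fnn(recs[1:32], recs[33:40],
                 trial_config(hidden_layers = 2, neurons_per_layer = 100),
                 seed = 2)
  hc <- hybrid_composite(recs, m, dft_fraction = 0.25)
  expect_equal(sum(hc$report$source == "reference"), 10)
  # lowest_energy rule keeps references on the lowest-energy conformers
  expect_true(all(hc$report$source[order(hc$report$energy)[1:10]] ==
                    "reference"))
  expect_gt(hc$theta, 0.9)

  rnd <- hybrid_composite(recs, m, dft_fraction = 0.25, selection = "random",
                          seed = 7)
  rnd2 <- hybrid_composite(recs, m, dft_fraction = 0.25,
                           selection = "random", seed = 7)
  expect_identical(rnd$spectrum$values, rnd2$spectrum$values)

  norefs <- recs
  norefs[[1]]$spectrum <- NULL
  norefs[[1]]$energy <- -5   # forces selection of the missing record
  expect_error(hybrid_composite(norefs, m, dft_fraction = 0.25),
               "no reference spectrum")
  expect_error(hybrid_composite(recs, m, dft_fraction = 0), "dft_fraction")
})

test_that("composite fidelity rises with the reference fraction (Monte Carlo)", {
  cfg <- synthetic_map_config(4, n_modes = 20, seed = 3)
  e <- generate_ensemble(150, cfg)
  recs <- ensemble_records(e, grid = small_grid())
  parts <- split_dataset(length(recs), split_spec(seed = 1))
  m <- train_fnn(recs[parts$train], recs[parts$validation],
                 trial_config(hidden_layers = 2, neurons_per_layer = 100),
                 seed = 4)
  tab <- benchmark_fractions(recs, m, fractions = c(0.1, 0.5, 0.9),
                             n_seeds = 5, seed = 2)
  expect_equal(nrow(tab), 3)
  expect_gte(tab$theta_median[3], tab$theta_median[1])
  expect_true(all(diff(tab$theta_median) > -0.02))
  expect_equal(tab$speedup, c(10, 2, 150 / 135), tolerance = 1e-12)
})
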