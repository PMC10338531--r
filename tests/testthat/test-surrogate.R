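# Dataset splitting, augmentation, training, prediction, evaluation.

test_that("split sizes follow round-then-remainder and the default 80:10:10", {
  s <- split_dataset(100, split_spec(seed = 4))
  expect_equal(lengths(s), c(train = 80L, validation = 10L, test = 10L))
  s2 <- split_dataset(10, split_spec(c(0.8, 0.1, 0.1), seed = 4))
  expect_equal(lengths(s2), c(train = 8L, validation = 1L, test = 1L))
  expect_error(split_spec(c(0.8, 0.1, 0.2)), "sum to 1")
})

test_that("splits are seed-reproducible, disjoint and exhaustive (randomized)", {
  a <- split_dataset(57, split_spec(seed = 8))
  b <- split_dataset(57, split_spec(seed = 8))
  expect_identical(a, b)
  c1 <- split_dataset(57, split_spec(seed = 9))
  expect_false(identical(a, c1))

  set.seed(6)
  for (i in 1:30) {
    n <- sample(3:200, 1)
    f1 <- runif(1, 0.3, 0.8)
    f2 <- runif(1, 0.05, min(0.3, 1 - f1))
    sp <- split_spec(c(f1, f2, 1 - f1 - f2), seed = i)
    s <- split_dataset(n, sp)
    all_idx <- sort(c(s$train, s$validation, s$test))
    expect_identical(all_idx, seq_len(n))
    expect_equal(length(s$train), round(n * f1))
  }
})

test_that("degenerate-pair partners are co-partitioned", {
  pm <- list(c(1L, 11L), c(2L, 12L), c(3L, 13L))
  for (seed in 1:10) {
    s <- split_dataset(20, split_spec(seed = seed), pair_map = pm)
    expect_identical(sort(unname(unlist(s))), 1:20)
    for (p in pm) {
      part <- vapply(s, function(idx) all(p %in% idx), logical(1))
      expect_equal(sum(part), 1L)
    }
  }
  expect_error(split_dataset(20, split_spec(seed = 1),
                             pair_map = list(c(1L, 25L))),
               "invalid")
})

test_that("degenerate-pair augmentation appends partner features with identical spectra", {
  recs <- linear_map_records(6)
  expect_identical(augment_degenerate_pairs(recs, list()), recs)
  partner <- mirror_features(recs[[2]]$features)
  out <- augment_degenerate_pairs(recs, setNames(list(partner),
                                                 recs[[2]]$id))
  expect_length(out, 7)
  added <- out[[7]]
  expect_identical(added$spectrum, recs[[2]]$spectrum)
  expect_identical(as.numeric(added$features), as.numeric(partner))
  expect_error(augment_degenerate_pairs(recs, list(nope = partner)),
               "unknown record id")
})

test_that("enantiomer augmentation doubles the set with mirrored members", {
  recs <- linear_map_records(5)
  out <- augment_with_enantiomers(recs)
  expect_length(out, 10)
  expect_equal(out[[6]]$spectrum$values, -recs[[1]]$spectrum$values)
  expect_equal(as.numeric(out[[6]]$features),
               as.numeric(mirror_features(recs[[1]]$features)))
})

test_that("sampled trial configurations always lie inside the search space", {
  space <- hyperparameter_space()
  set.seed(77)
  for (i in 1:200) {
    cfg <- sample_trial_config(space)
    expect_true(validate_trial_config(cfg, space))
  }
  expect_error(validate_trial_config(trial_config(hidden_layers = 9), space),
               "hidden_layers")
  expect_error(validate_trial_config(trial_config(learning_rate = 0.5),
                                     space),
               "learning_rate")
})

test_that("the surrogate learns a constant target to high precision", {
  # pure optimization check: validation shares the training conformers, so
  # the loss must be drivable to ~0 within the epoch budget
  grid <- small_grid()
  target <- vcd_spectrum(grid, sin(seq_len(grid$points)))
  set.seed(0)
  recs <- lapply(1:16, function(i)
    list(id = paste0("c", i),
         features = encode_dihedrals(runif(3, -180, 180)),
         energy = 0, spectrum = target, source = "reference"))
  m <- train_fnn(recs, recs[1:4],
                 trial_config(hidden_layers = 1, neurons_per_layer = 50,
                              learning_rate = 5e-3),
                 seed = 2, control = fnn_control(standardize_y = FALSE))
  expect_lt(m$val_mse, 1e-4 * mean(target$values^2))
  ev <- evaluate_surrogate(m, recs[1:4])
  expect_gt(ev$median, 0.999)
})

test_that("the surrogate recovers a linear sincos map on held-out conformers", {
  recs <- linear_map_records(300, d = 3, seed = 5)
  parts <- split_dataset(length(recs), split_spec(seed = 1))
  m <- train_fnn(recs[parts$train], recs[parts$validation],
                 trial_config(hidden_layers = 2, neurons_per_layer = 100),
                 seed = 3)
  ev <- evaluate_surrogate(m, recs[parts$test])
  expect_gte(ev$median, 0.99)
  # a training-set record should fit at least as well as held-out ones
  ev_train <- evaluate_surrogate(m, recs[parts$train])
  expect_gte(ev_train$median, ev$median - 1e-6)
})

test_that("early stopping halts patience epochs after the best epoch and restores it", {
  # small noisy problem that overfits quickly, so stopping fires early
  set.seed(9)
  grid <- small_grid()
  mk <- function(n) lapply(seq_len(n), function(i)
    list(id = paste0("r", i),
         features = encode_dihedrals(runif(2, -180, 180)),
         energy = 0,
         spectrum = vcd_spectrum(grid, rnorm(grid$points)),
         source = "reference"))
  m <- train_fnn(mk(8), mk(8), trial_config(neurons_per_layer = 60),
                 seed = 4, control = fnn_control(max_epochs = 400))
  expect_lt(nrow(m$log), 400)
  expect_equal(nrow(m$log), m$best_epoch + m$config$patience)
  expect_equal(m$val_mse, min(m$log$val_mse))
})

test_that("prediction is deterministic, grid-sized and layout-checked", {
  recs <- linear_map_records(30, grid = vcd_grid())
  m <- train_fnn(recs[1:24], recs[25:30],
                 trial_config(hidden_layers = 1, neurons_per_layer = 50),
                 seed = 6, control = fnn_control(max_epochs = 30))
  p1 <- predict(m, recs[[1]]$features)
  p2 <- predict(m, recs[[1]]$features)
  expect_identical(p1$values, p2$values)
  expect_length(p1$values, 101L)

  wrong <- setNames(as.numeric(recs[[1]]$features),
                    rev(names(recs[[1]]$features)))
  wrong <- matrix(wrong, 1, dimnames = list(NULL, names(wrong)))
  expect_error(predict(m, wrong), "layout mismatch at slot 1")
})

test_that("training rejects inconsistent inputs and evaluation needs references", {
  recs <- linear_map_records(12)
  other <- linear_map_records(4, d = 2, seed = 6)
  expect_error(train_fnn(recs[1:8], other, trial_config(), seed = 1),
               "layout")
  m <- train_fnn(recs[1:8], recs[9:12],
                 trial_config(hidden_layers = 1, neurons_per_layer = 50),
                 seed = 1, control = fnn_control(max_epochs = 5))
  norefs <- lapply(recs[1:3], function(r) { r$spectrum <- NULL; r })
  expect_error(evaluate_surrogate(m, norefs), "no reference spectrum")
  ev <- evaluate_surrogate(m, recs)
  expect_true(all(ev$similarities$similarity >= -1 &
                    ev$similarities$similarity <= 1))
})

test_that("a model trained with degenerate pairs predicts equal spectra for partners", {
  cfg <- synthetic_map_config(4, n_modes = 15, coupling_order = 1,
                              seed = 44)
  e <- generate_ensemble(160, cfg, degenerate_pairs = TRUE)
  recs <- ensemble_records(e, grid = small_grid())
  parts <- split_dataset(length(recs), split_spec(seed = 2),
                         pair_map = e$pair_map)
  m <- train_fnn(recs[parts$train], recs[parts$validation],
                 trial_config(hidden_layers = 2, neurons_per_layer = 200,
                              learning_rate = 2e-3),
                 seed = 5, control = fnn_control(batch_size = 64))
  train_pairs <- Filter(function(p) all(p %in% parts$train), e$pair_map)
  expect_gt(length(train_pairs), 0)
  sims <- vapply(train_pairs, function(p) {
    pa <- predict(m, recs[[p[1]]]$features)
    pb <- predict(m, recs[[p[2]]]$features)
    cosine_similarity(pa, pb)
  }, numeric(1))
  expect_gt(median(sims), 0.99)
})
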