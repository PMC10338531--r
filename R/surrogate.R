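# The geometry -> spectrum surrogate: dataset splitting, symmetry
# augmentation, FNN training with early stopping, prediction and
# cosine-similarity evaluation.

#' Train/validation/test split specification
#'
#' @param fractions Numeric length-3 `(train, validation, test)` summing to 1
#'   (tolerance 1e-12); default `c(0.80, 0.10, 0.10)`.
#' @param seed Integer seed making the split reproducible.
#' @return A `split_spec` object.
#' @export
split_spec <- function(fractions = c(0.80, 0.10, 0.10), seed = 1) {
  stopifnot(is.numeric(fractions), length(fractions) == 3,
            all(fractions >= 0), all(fractions <= 1))
  if (abs(sum(fractions) - 1) > 1e-12)
    stop("split fractions must sum to 1, got ", sum(fractions))
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

#' Random dataset split
#'
#' Partitions record indices `1..n` into disjoint, exhaustive train,
#' validation and test sets. Sizes are `round(n * f_train)` and
#' `round(n * f_val)`, with the remainder going to test (so the default
#' 80:10:10 split of 100 records gives 80/10/10). When a `pair_map` of
#' degenerate-pair partners is supplied, both members of a pair are kept in
#' the same partition to prevent symmetry-duplicate leakage across splits
#' (partition sizes then match the targets as closely as the pairing
#' allows).
#'
#' @param n_records Number of records (>= 3).
#' @param spec A [split_spec()].
#' @param pair_map Optional list of length-2 integer vectors of paired
#'   record indices.
#' @return Named list of integer index vectors `train`, `validation`,
#'   `test`.
#' @export
split_dataset <- function(n_records, spec = split_spec(), pair_map = NULL) {
  stopifnot(inherits(spec, "split_spec"), n_records >= 3)
  n <- as.integer(n_records)
  n_train <- round(n * spec$fractions[1])
  n_val <- round(n * spec$fractions[2])
  if (n_train + n_val > n) n_val <- n - n_train
  with_seed(spec$seed, {
    if (is.null(pair_map) || length(pair_map) == 0) {
      perm <- sample.int(n)
      list(train = sort(perm[seq_len(n_train)]),
           validation = sort(perm[n_train + seq_len(n_val)]),
           test = sort(perm[setdiff(seq_len(n), seq_len(n_train + n_val))]))
    } else {
      idx <- unlist(pair_map)
      if (any(idx < 1) || any(idx > n) || anyDuplicated(idx))
        stop("pair_map references invalid or duplicated record indices")
      units <- c(pair_map, as.list(setdiff(seq_len(n), idx)))
      units <- units[sample.int(length(units))]
      assign_to <- character(0)
      counts <- c(train = 0L, validation = 0L, test = 0L)
      targets <- c(train = n_train, validation = n_val,
                   test = n - n_train - n_val)
      out <- list(train = integer(0), validation = integer(0),
                  test = integer(0))
      for (u in units) {
        deficit <- targets - counts
        part <- names(which.max(deficit))
        out[[part]] <- c(out[[part]], u)
        counts[part] <- counts[part] + length(u)
      }
      lapply(out, sort)
    }
  })
}

records_check <- function(records, need_spectrum = FALSE) {
  stopifnot(is.list(records), length(records) > 0)
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r$features) || is.null(attr(r$features, "slot_type")))
      stop("record ", i, " has no typed feature vector")
    if (need_spectrum && !inherits(r$spectrum, "vcd_spectrum"))
      stop("record ", i, " (", r$id, ") carries no reference spectrum")
  }
  invisible(records)
}

records_features <- function(records) {
  X <- do.call(rbind, lapply(records, function(r) as.numeric(r$features)))
  colnames(X) <- names(records[[1]]$features)
  X
}

records_targets <- function(records) {
  do.call(rbind, lapply(records, function(r) r$spectrum$values))
}

#' Duplicate degenerate conformer pairs into the training data
#'
#' Geometrically distinct conformers related by an internal symmetry share
#' one VCD spectrum but present different feature vectors. The model is
#' taught this equivalence by explicitly appending, for every mapped record,
#' a duplicate record carrying the symmetry partner's features together with
#' the identical spectrum.
#'
#' @param records List of conformer records.
#' @param pair_map Named list: record id -> the partner's feature vector
#'   (a `vcd_features` object). May be empty.
#' @return The record list with one appended duplicate per map entry.
#' @export
augment_degenerate_pairs <- function(records, pair_map) {
  records_check(records)
  if (length(pair_map) == 0) return(records)
  ids <- vapply(records, function(r) r$id, character(1))
  for (id in names(pair_map)) {
    j <- match(id, ids)
    if (is.na(j)) stop("pair_map references unknown record id: ", id)
    dup <- records[[j]]
    dup$id <- paste0(id, "_sympartner")
    dup$features <- pair_map[[id]]
    records[[length(records) + 1]] <- dup
  }
  records
}

#' Enantiomer data augmentation
#'
#' Appends, for every record, its mirror image: features transformed by the
#' enantiomer rule ([mirror_features()]) and the reference spectrum negated
#' ([mirror_spectrum()]). Training on the doubled set teaches the model the
#' mirror-image relationship between enantiomer spectra, which a model
#' trained on a single enantiomer does not pick up.
#'
#' @param records List of conformer records with reference spectra.
#' @return A list of `2n` records.
#' @export
augment_with_enantiomers <- function(records) {
  records_check(records, need_spectrum = TRUE)
  mirrored <- lapply(records, function(r) {
    r$id <- paste0(r$id, "_ent")
    r$features <- mirror_features(r$features)
    r$spectrum <- mirror_spectrum(r$spectrum)
    r
  })
  c(records, mirrored)
}

#' Hyperparameter search space for the FNN
#'
#' The default search space for Bayesian optimization of the surrogate
#' architecture and training configuration: 1-8 hidden layers of 50-500
#' neurons (steps of 10), dropout 0-0.20, four activations, four optimizers,
#' log-uniform learning rate in `[1e-5, 1e-2]`, optional batch
#' normalization, L1 or L2 regularization with log-uniform strength in
#' `[1e-9, 1e-4]`, and a fixed early-stopping patience of 5 epochs.
#'
#' @return A `hyperparameter_space` object (named list of value sets and
#'   `*_range` intervals sampled on a log scale).
#' @export
hyperparameter_space <- function() {
  structure(list(
    hidden_layers = 1:8,
    neurons_per_layer = seq(50L, 500L, by = 10L),
    dropout_rate = c(0, 0.05, 0.10, 0.15, 0.20),
    activation = c("tanh", "elu", "relu", "selu"),
    optimizer = c("adam", "nadam", "rmsprop", "nesterov momentum"),
    learning_rate_range = c(1e-5, 1e-2),
    batch_normalization = c(TRUE, FALSE),
    regularization = c("L1", "L2"),
    regularization_strength_range = c(1e-9, 1e-4),
    patience = 5L
  ), class = "hyperparameter_space")
}

#' One concrete surrogate configuration
#'
#' @param hidden_layers Number of hidden layers.
#' @param neurons_per_layer Units per hidden layer.
#' @param dropout_rate Dropout rate in the hidden layers.
#' @param activation One of `"tanh"`, `"elu"`, `"relu"`, `"selu"`.
#' @param optimizer One of `"adam"`, `"nadam"`, `"rmsprop"`,
#'   `"nesterov momentum"` (SGD with Nesterov momentum 0.9).
#' @param learning_rate Optimizer learning rate.
#' @param batch_normalization Logical.
#' @param regularization `"L1"` or `"L2"` weight penalty.
#' @param regularization_strength Penalty coefficient.
#' @param patience Early-stopping patience in epochs (default 5).
#' @return A `trial_config` object.
#' @export
trial_config <- function(hidden_layers = 3, neurons_per_layer = 200,
                         dropout_rate = 0, activation = "relu",
                         optimizer = "adam", learning_rate = 1e-3,
                         batch_normalization = FALSE,
                         regularization = "L2",
                         regularization_strength = 1e-9,
                         patience = 5) {
  structure(list(hidden_layers = as.integer(hidden_layers),
                 neurons_per_layer = as.integer(neurons_per_layer),
                 dropout_rate = dropout_rate, activation = activation,
                 optimizer = optimizer, learning_rate = learning_rate,
                 batch_normalization = batch_normalization,
                 regularization = regularization,
                 regularization_strength = regularization_strength,
                 patience = as.integer(patience)),
            class = "trial_config")
}

#' Check that a configuration lies inside a search space
#'
#' @param cfg A [trial_config()].
#' @param space A [hyperparameter_space()].
#' @return `TRUE` invisibly; an error naming the offending dimension
#'   otherwise.
#' @export
validate_trial_config <- function(cfg, space = hyperparameter_space()) {
  stopifnot(inherits(cfg, "trial_config"),
            inherits(space, "hyperparameter_space"))
  in_set <- function(nm) {
    if (!cfg[[nm]] %in% space[[nm]])
      stop("trial config ", nm, " = ", cfg[[nm]], " outside the search space")
  }
  for (nm in c("hidden_layers", "neurons_per_layer", "dropout_rate",
               "activation", "optimizer", "batch_normalization",
               "regularization"))
    in_set(nm)
  in_range <- function(nm) {
    r <- space[[paste0(nm, "_range")]]
    if (cfg[[nm]] < r[1] || cfg[[nm]] > r[2])
      stop("trial config ", nm, " = ", cfg[[nm]], " outside [",
           r[1], ", ", r[2], "]")
  }
  in_range("learning_rate")
  in_range("regularization_strength")
  if (cfg$patience != space$patience)
    stop("trial config patience must be ", space$patience)
  invisible(TRUE)
}

#' Sample one configuration uniformly from the search space
#'
#' Categorical dimensions are drawn uniformly from their value sets;
#' learning rate and regularization strength are drawn log-uniformly from
#' their intervals. Uses the current RNG stream.
#'
#' @param space A [hyperparameter_space()].
#' @return A [trial_config()].
#' @export
sample_trial_config <- function(space = hyperparameter_space()) {
  log_unif <- function(r) exp(runif(1, log(r[1]), log(r[2])))
  trial_config(
    hidden_layers = sample(space$hidden_layers, 1),
    neurons_per_layer = sample(space$neurons_per_layer, 1),
    dropout_rate = sample(space$dropout_rate, 1),
    activation = sample(space$activation, 1),
    optimizer = sample(space$optimizer, 1),
    learning_rate = log_unif(space$learning_rate_range),
    batch_normalization = sample(space$batch_normalization, 1),
    regularization = sample(space$regularization, 1),
    regularization_strength = log_unif(space$regularization_strength_range),
    patience = space$patience)
}

#' Training control settings
#'
#' Epoch ceiling, minibatch size and output scaling for [train_fnn()]. The
#' patience-5 early-stopping rule usually halts training well before the
#' epoch ceiling.
#'
#' @param max_epochs Epoch ceiling (default 500).
#' @param batch_size Minibatch size (default 32).
#' @param standardize_y Standardize each output channel (z-score with
#'   training-split statistics) during training and de-standardize at
#'   prediction (default TRUE); without it the squared-error loss
#'   over-weights strong bands.
#' @return A `fnn_control` list.
#' @export
fnn_control <- function(max_epochs = 500, batch_size = 32,
                        standardize_y = TRUE) {
  stopifnot(max_epochs >= 1, batch_size >= 1)
  list(max_epochs = as.integer(max_epochs),
       batch_size = as.integer(batch_size),
       standardize_y = isTRUE(standardize_y))
}

#' Train the feed-forward surrogate
#'
#' Fits a fully connected network with `cfg$hidden_layers` hidden layers of
#' `cfg$neurons_per_layer` units and a linear output head of one unit per
#' grid point, minimizing mean squared error with the configured optimizer.
#' Hydrogen-bond distance slots are min-max scaled and (optionally) output
#' channels z-scored, both using training-split statistics only. Training
#' stops when the validation MSE has not improved for `cfg$patience`
#' consecutive epochs and the best-validation parameters are restored.
#'
#' @param train_records,val_records Nonempty record lists with consistent
#'   feature layouts and reference spectra on a common grid.
#' @param cfg A [trial_config()].
#' @param seed Integer seed governing weight initialization, minibatch
#'   shuffling and dropout.
#' @param control A [fnn_control()] list.
#' @return A `vcd_surrogate` object holding the architecture, learned
#'   parameters, input layout, output grid, preprocessing statistics and the
#'   per-epoch training log.
#' @export
train_fnn <- function(train_records, val_records, cfg = trial_config(),
                      seed = 1, control = fnn_control()) {
  stopifnot(inherits(cfg, "trial_config"))
  records_check(train_records, need_spectrum = TRUE)
  records_check(val_records, need_spectrum = TRUE)
  layout <- names(train_records[[1]]$features)
  types <- attr(train_records[[1]]$features, "slot_type")
  for (r in c(train_records, val_records))
    if (!identical(names(r$features), layout))
      stop("inconsistent feature layout across records (record ", r$id, ")")
  grid <- train_records[[1]]$spectrum$grid
  for (r in c(train_records, val_records))
    if (!grids_identical(r$spectrum$grid, grid))
      stop("inconsistent spectrum grid across records (record ", r$id, ")")

  X <- records_features(train_records)
  Y <- records_targets(train_records)
  Xv <- records_features(val_records)
  Yv <- records_targets(val_records)

  dist_idx <- which(types == "dist")
  x_scale <- NULL
  if (length(dist_idx)) {
    lo <- apply(X[, dist_idx, drop = FALSE], 2, min)
    hi <- apply(X[, dist_idx, drop = FALSE], 2, max)
    rng <- pmax(hi - lo, 1e-12)
    x_scale <- list(idx = dist_idx, lo = lo, rng = rng)
    X[, dist_idx] <- sweep(sweep(X[, dist_idx, drop = FALSE], 2, lo), 2, rng, "/")
    Xv[, dist_idx] <- sweep(sweep(Xv[, dist_idx, drop = FALSE], 2, lo), 2, rng, "/")
  }
  y_center <- rep(0, ncol(Y))
  y_scale <- rep(1, ncol(Y))
  if (control$standardize_y) {
    y_center <- colMeans(Y)
    y_scale <- pmax(apply(Y, 2, sd), 1e-12)
    Y <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")
    Yv <- sweep(sweep(Yv, 2, y_center), 2, y_scale, "/")
  }

  fit <- with_seed(seed, {
    params <- mlp_init(ncol(X), ncol(Y), cfg)
    mlp_train_loop(params, X, Y, Xv, Yv, cfg,
                   control$max_epochs, control$batch_size)
  })
  structure(list(config = cfg, params = fit$params, input_layout = layout,
                 slot_type = types, grid = grid, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 log = fit$log, best_epoch = fit$best_epoch,
                 val_mse = fit$best_val, seed = seed, control = control),
            class = "vcd_surrogate")
}

#' @export
print.vcd_surrogate <- function(x, ...) {
  cat(sprintf(
    "<vcd_surrogate> %d x %d %s net, %d -> %d; best val MSE %.4g (epoch %d/%d)\n",
    x$config$hidden_layers, x$config$neurons_per_layer, x$config$activation,
    length(x$input_layout), x$grid$points, x$val_mse, x$best_epoch,
    nrow(x$log)))
  invisible(x)
}

surrogate_feature_matrix <- function(object, newdata) {
  if (inherits(newdata, "vcd_features"))
    newdata <- matrix(as.numeric(newdata), 1,
                      dimnames = list(NULL, names(newdata)))
  if (is.list(newdata) && !is.matrix(newdata) && !is.data.frame(newdata))
    newdata <- records_features(newdata)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object$input_layout))
    colnames(newdata) <- object$input_layout
  if (!identical(colnames(newdata), object$input_layout)) {
    bad <- which(colnames(newdata) != object$input_layout)[1]
    stop(sprintf(
      "feature layout mismatch at slot %d: model expects '%s', got '%s'",
      bad, object$input_layout[bad], colnames(newdata)[bad]))
  }
  if (!is.null(object$x_scale)) {
    s <- object$x_scale
    newdata[, s$idx] <- sweep(sweep(newdata[, s$idx, drop = FALSE], 2, s$lo),
                              2, s$rng, "/")
  }
  newdata
}

#' Predict VCD spectra with a trained surrogate
#'
#' Deterministic inference-mode forward pass (dropout off, batch
#' normalization with running statistics); identical input always yields
#' identical output.
#'
#' @param object A `vcd_surrogate` from [train_fnn()].
#' @param newdata A single `vcd_features` vector, a feature matrix (one row
#'   per conformer, columns matching the model's input layout), or a list of
#'   conformer records.
#' @param ... Unused.
#' @return A single [vcd_spectrum()] for a single feature vector, otherwise
#'   a list of spectra on the model's grid.
#' @export
predict.vcd_surrogate <- function(object, newdata, ...) {
  single <- inherits(newdata, "vcd_features")
  X <- surrogate_feature_matrix(object, newdata)
  out <- mlp_forward(object$params, X, object$config, training = FALSE)$out
  out <- sweep(sweep(out, 2, object$y_scale, "*"), 2, object$y_center, "+")
  spectra <- lapply(seq_len(nrow(out)), function(i)
    vcd_spectrum(object$grid, out[i, ]))
  if (single) spectra[[1]] else spectra
}

#' Evaluate a surrogate against reference spectra
#'
#' Computes the per-record cosine similarity between the predicted and
#' reference spectrum (the quantity shown as violin distributions in
#' conformer-level benchmarks) plus summary statistics.
#'
#' @param model A `vcd_surrogate`.
#' @param records Record list; every record must carry a reference spectrum.
#' @return A list with `similarities` (data frame of id, similarity),
#'   `median` and `min`.
#' @export
evaluate_surrogate <- function(model, records) {
  records_check(records, need_spectrum = TRUE)
  preds <- predict(model, records)
  sims <- vapply(seq_along(records), function(i)
    cosine_similarity(preds[[i]], records[[i]]$spectrum), numeric(1))
  ids <- vapply(records, function(r) r$id, character(1))
  list(similarities = data.frame(id = ids, similarity = sims),
       median = median(sims), min = min(sims))
}
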