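# Tree-structured Parzen estimator (TPE) for hyperparameter search.
#
# After a random start-up phase, observed trials are split by validation
# loss into a "good" quantile and the rest. Each search dimension gets a
# pair of density estimates l(x) (good) and g(x) (bad): weighted categorical
# frequencies with a unit prior for discrete dimensions, Gaussian kernel
# densities in log space for the two continuous ones. Candidates are drawn
# from the good densities and the one maximizing the likelihood ratio
# l(x)/g(x) becomes the next trial.

TPE_STARTUP <- 10L
TPE_GAMMA <- 0.25
TPE_CANDIDATES <- 24L

tpe_cat_probs <- function(values, choices) {
  counts <- table(factor(as.character(values), levels = as.character(choices)))
  p <- (as.numeric(counts) + 1) / (length(values) + length(choices))
  setNames(p, as.character(choices))
}

tpe_kde <- function(x_log, bounds_log) {
  bw <- max(1.06 * sd(x_log) * length(x_log)^(-0.2),
            diff(bounds_log) / 50)
  list(centers = x_log, bw = bw, bounds = bounds_log)
}

tpe_kde_density <- function(kde, x_log) {
  mean(dnorm(x_log, kde$centers, kde$bw)) + 1e-12
}

tpe_kde_sample <- function(kde) {
  x <- rnorm(1, sample(kde$centers, 1), kde$bw)
  min(max(x, kde$bounds[1]), kde$bounds[2])
}

tpe_propose <- function(space, configs, losses) {
  ord <- order(losses)
  n_good <- max(1L, ceiling(TPE_GAMMA * length(losses)))
  good <- configs[ord[seq_len(n_good)]]
  bad <- configs[ord[-seq_len(n_good)]]
  if (length(bad) == 0) bad <- configs

  cat_dims <- c("hidden_layers", "neurons_per_layer", "dropout_rate",
                "activation", "optimizer", "batch_normalization",
                "regularization")
  cat_models <- lapply(setNames(nm = cat_dims), function(nm) {
    vals_g <- sapply(good, `[[`, nm)
    vals_b <- sapply(bad, `[[`, nm)
    list(l = tpe_cat_probs(vals_g, space[[nm]]),
         g = tpe_cat_probs(vals_b, space[[nm]]),
         choices = space[[nm]])
  })
  num_dims <- c("learning_rate", "regularization_strength")
  num_models <- lapply(setNames(nm = num_dims), function(nm) {
    bounds <- log(space[[paste0(nm, "_range")]])
    list(l = tpe_kde(log(sapply(good, `[[`, nm)), bounds),
         g = tpe_kde(log(sapply(bad, `[[`, nm)), bounds))
  })

  best_score <- -Inf
  best_cfg <- NULL
  for (k in seq_len(TPE_CANDIDATES)) {
    cand <- list(patience = space$patience)
    score <- 0
    for (nm in cat_dims) {
      m <- cat_models[[nm]]
      pick <- sample(seq_along(m$choices), 1, prob = m$l)
      cand[[nm]] <- m$choices[pick]
      score <- score + log(m$l[pick]) - log(m$g[pick])
    }
    for (nm in num_dims) {
      m <- num_models[[nm]]
      xl <- tpe_kde_sample(m$l)
      r <- space[[paste0(nm, "_range")]]
      cand[[nm]] <- min(max(exp(xl), r[1]), r[2])
      score <- score + log(tpe_kde_density(m$l, xl)) -
        log(tpe_kde_density(m$g, xl))
    }
    if (score > best_score) {
      best_score <- score
      best_cfg <- cand
    }
  }
  do.call(trial_config, best_cfg)
}

#' Bayesian hyperparameter optimization of the surrogate
#'
#' Runs `n_trials` training trials, each with a configuration proposed by a
#' tree-structured Parzen estimator over the search space (uniform random
#' sampling for the first few start-up trials), and returns the
#' configuration with the lowest validation MSE. The whole run is
#' reproducible from `seed`; the trial-sampling, weight-initialization and
#' split streams are derived independently, so runs with a larger budget
#' share their leading trials with smaller-budget runs of the same seed.
#'
#' @param train_records,val_records Record lists as for [train_fnn()].
#' @param space A [hyperparameter_space()].
#' @param n_trials Number of trials (>= 1); default 50.
#' @param seed Integer master seed.
#' @param control A [fnn_control()] passed to every trial; trials are
#'   typically run with a reduced `max_epochs`.
#' @param objective Optional function `(config, seed) -> loss` replacing the
#'   default "train and report validation MSE" objective (used for cheap
#'   search-behaviour studies).
#' @return List with `best_config`, `best_loss`, `configs` (list of all
#'   trial configurations) and `history` (data frame of trial, loss).
#' @export
optimize_hyperparameters <- function(train_records, val_records,
                                     space = hyperparameter_space(),
                                     n_trials = 50, seed = 1,
                                     control = fnn_control(),
                                     objective = NULL) {
  stopifnot(inherits(space, "hyperparameter_space"))
  if (n_trials < 1) stop("empty search budget: n_trials must be >= 1")
  if (is.null(objective))
    objective <- function(cfg, trial_seed)
      train_fnn(train_records, val_records, cfg, seed = trial_seed,
                control = control)$val_mse
  seeds <- derive_seeds(seed, 2L * n_trials)
  sampler_seeds <- seeds[seq_len(n_trials)]
  trial_seeds <- seeds[n_trials + seq_len(n_trials)]
  configs <- vector("list", n_trials)
  losses <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    configs[[t]] <- with_seed(sampler_seeds[t], {
      if (t <= TPE_STARTUP) sample_trial_config(space)
      else tpe_propose(space, configs[seq_len(t - 1)],
                       losses[seq_len(t - 1)])
    })
    validate_trial_config(configs[[t]], space)
    losses[t] <- objective(configs[[t]], trial_seeds[t])
  }
  best <- which.min(losses)
  list(best_config = configs[[best]], best_loss = losses[best],
       configs = configs,
       history = data.frame(trial = seq_len(n_trials), loss = losses))
}
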