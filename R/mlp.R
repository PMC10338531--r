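# Internal multilayer-perceptron engine: dense layers with optional batch
# normalization and dropout, four optimizers, L1/L2 weight penalties,
# minibatch training with patience-based early stopping. Written against
# plain base-R matrices; sizes in this package (hundreds of samples, a few
# hundred units, 101 outputs) are small enough that BLAS-backed %*% carries
# the cost.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.99

activation_pair <- function(name) {
  switch(name,
    tanh = list(f = function(z) tanh(z),
                df = function(z, a) 1 - a * a),
    relu = list(f = function(z) pmax(z, 0),
                df = function(z, a) (z > 0) * 1),
    elu = list(f = function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
               df = function(z, a) ifelse(z > 0, 1, a + 1)),
    selu = {
      lam <- 1.0507009873554805; alp <- 1.6732632423543772
      list(f = function(z) lam * ifelse(z > 0, z, alp * (exp(pmin(z, 0)) - 1)),
           df = function(z, a) lam * ifelse(z > 0, 1, alp * exp(pmin(z, 0))))
    },
    stop("unknown activation: ", name))
}

glorot_init <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

mlp_init <- function(d_in, d_out, cfg) {
  sizes <- c(d_in, rep(cfg$neurons_per_layer, cfg$hidden_layers))
  layers <- lapply(seq_len(cfg$hidden_layers), function(i) {
    l <- list(W = glorot_init(sizes[i], sizes[i + 1]),
              b = numeric(sizes[i + 1]))
    if (isTRUE(cfg$batch_normalization)) {
      l$gamma <- rep(1, sizes[i + 1])
      l$beta <- numeric(sizes[i + 1])
      l$run_mean <- numeric(sizes[i + 1])
      l$run_var <- rep(1, sizes[i + 1])
    }
    l
  })
  out <- list(W = glorot_init(sizes[length(sizes)], d_out),
              b = numeric(d_out))
  list(layers = layers, out = out)
}

# Forward pass. Returns output, per-layer caches for backprop, and (during
# training with batch norm) updated running statistics.
mlp_forward <- function(params, X, cfg, training = FALSE) {
  act <- activation_pair(cfg$activation)
  caches <- vector("list", length(params$layers))
  H <- X
  for (i in seq_along(params$layers)) {
    l <- params$layers[[i]]
    Z <- H %*% l$W
    Z <- sweep(Z, 2, l$b, "+")
    cache <- list(X_in = H)
    if (!is.null(l$gamma)) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(Z * Z) - mu * mu
        params$layers[[i]]$run_mean <- BN_MOMENTUM * l$run_mean + (1 - BN_MOMENTUM) * mu
        params$layers[[i]]$run_var <- BN_MOMENTUM * l$run_var + (1 - BN_MOMENTUM) * v
      } else {
        mu <- l$run_mean
        v <- l$run_var
      }
      inv <- 1 / sqrt(v + BN_EPS)
      Zh <- sweep(sweep(Z, 2, mu, "-"), 2, inv, "*")
      Zb <- sweep(sweep(Zh, 2, l$gamma, "*"), 2, l$beta, "+")
      cache$Zh <- Zh
      cache$inv <- inv
    } else {
      Zb <- Z
    }
    A <- act$f(Zb)
    cache$Zb <- Zb
    cache$A_act <- A
    if (training && cfg$dropout_rate > 0) {
      keep <- 1 - cfg$dropout_rate
      mask <- (matrix(runif(length(A)), nrow(A), ncol(A)) < keep) / keep
      A <- A * mask
      cache$mask <- mask
    }
    caches[[i]] <- cache
    H <- A
  }
  out <- sweep(H %*% params$out$W, 2, params$out$b, "+")
  list(out = out, H_last = H, caches = caches, params = params)
}

# Backward pass for mean-squared-error loss gradient dOut (n x d_out).
mlp_backward <- function(params, fw, dOut, cfg) {
  act <- activation_pair(cfg$activation)
  grads <- list(out = list(W = crossprod(fw$H_last, dOut),
                           b = colSums(dOut)),
                layers = vector("list", length(params$layers)))
  dA <- dOut %*% t(params$out$W)
  for (i in rev(seq_along(params$layers))) {
    l <- params$layers[[i]]
    cache <- fw$caches[[i]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dZb <- dA * act$df(cache$Zb, cache$A_act)
    g <- list()
    if (!is.null(l$gamma)) {
      g$gamma <- colSums(dZb * cache$Zh)
      g$beta <- colSums(dZb)
      dZh <- sweep(dZb, 2, l$gamma, "*")
      mean_dZh <- colMeans(dZh)
      mean_dZh_Zh <- colMeans(dZh * cache$Zh)
      dZ <- sweep(sweep(dZh, 2, mean_dZh, "-") -
                    sweep(cache$Zh, 2, mean_dZh_Zh, "*"),
                  2, cache$inv, "*")
    } else {
      dZ <- dZb
    }
    g$W <- crossprod(cache$X_in, dZ)
    g$b <- colSums(dZ)
    grads$layers[[i]] <- g
    if (i > 1) dA <- dZ %*% t(l$W)
  }
  grads
}

# Add L1/L2 penalty gradients to the weight matrices (not biases or batch
# norm parameters), matching the loss  lambda * sum|W|  or  lambda * sum W^2.
add_reg_grads <- function(grads, params, cfg) {
  lam <- cfg$regularization_strength
  if (is.null(lam) || lam <= 0) return(grads)
  pen <- if (identical(cfg$regularization, "L1"))
    function(W) lam * sign(W) else function(W) 2 * lam * W
  for (i in seq_along(params$layers))
    grads$layers[[i]]$W <- grads$layers[[i]]$W + pen(params$layers[[i]]$W)
  grads$out$W <- grads$out$W + pen(params$out$W)
  grads
}

opt_state_like <- function(p) lapply(p, function(x) x * 0)

# One optimizer step for a single parameter array.
opt_step <- function(p, g, st, opt, lr, t) {
  if (opt == "adam" || opt == "nadam") {
    st$m <- 0.9 * st$m + 0.1 * g
    st$v <- 0.999 * st$v + 0.001 * g * g
    mhat <- st$m / (1 - 0.9^t)
    vhat <- st$v / (1 - 0.999^t)
    upd <- if (opt == "adam") mhat
           else 0.9 * mhat + 0.1 * g / (1 - 0.9^t)
    p <- p - lr * upd / (sqrt(vhat) + 1e-8)
  } else if (opt == "rmsprop") {
    st$v <- 0.9 * st$v + 0.1 * g * g
    p <- p - lr * g / (sqrt(st$v) + 1e-8)
  } else if (opt == "nesterov momentum") {
    st$m <- 0.9 * st$m - lr * g
    p <- p + 0.9 * st$m - lr * g
  } else {
    stop("unknown optimizer: ", opt)
  }
  list(p = p, st = st)
}

trainable_names <- function(l) intersect(names(l), c("W", "b", "gamma", "beta"))

mlp_train_loop <- function(params, X, Y, Xv, Yv, cfg, max_epochs, batch_size) {
  n <- nrow(X)
  d_out <- ncol(Y)
  lr <- cfg$learning_rate
  opt <- cfg$optimizer
  state <- list(
    layers = lapply(params$layers, function(l)
      lapply(setNames(nm = trainable_names(l)), function(nm)
        list(m = l[[nm]] * 0, v = l[[nm]] * 0))),
    out = lapply(setNames(nm = c("W", "b")), function(nm)
      list(m = params$out[[nm]] * 0, v = params$out[[nm]] * 0)))
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  t_step <- 0L
  log <- data.frame(epoch = integer(0), train_mse = numeric(0),
                    val_mse = numeric(0))
  for (epoch in seq_len(max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      bidx <- idx[s:min(s + batch_size - 1, n)]
      Xb <- X[bidx, , drop = FALSE]
      Yb <- Y[bidx, , drop = FALSE]
      fw <- mlp_forward(params, Xb, cfg, training = TRUE)
      params <- fw$params   # running BN statistics updated
      dOut <- 2 * (fw$out - Yb) / (nrow(Xb) * d_out)
      grads <- add_reg_grads(mlp_backward(params, fw, dOut, cfg), params, cfg)
      t_step <- t_step + 1L
      for (i in seq_along(params$layers)) {
        for (nm in trainable_names(params$layers[[i]])) {
          r <- opt_step(params$layers[[i]][[nm]], grads$layers[[i]][[nm]],
                        state$layers[[i]][[nm]], opt, lr, t_step)
          params$layers[[i]][[nm]] <- r$p
          state$layers[[i]][[nm]] <- r$st
        }
      }
      for (nm in c("W", "b")) {
        r <- opt_step(params$out[[nm]], grads$out[[nm]], state$out[[nm]],
                      opt, lr, t_step)
        params$out[[nm]] <- r$p
        state$out[[nm]] <- r$st
      }
    }
    train_mse <- mean((mlp_forward(params, X, cfg)$out - Y)^2)
    val_mse <- mean((mlp_forward(params, Xv, cfg)$out - Yv)^2)
    log <- rbind(log, data.frame(epoch = epoch, train_mse = train_mse,
                                 val_mse = val_mse))
    if (val_mse < best_val) {
      best_val <- val_mse
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  list(params = best_params, log = log, best_epoch = best_epoch,
       best_val = best_val)
}
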