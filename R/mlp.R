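# Multi-layer perceptron for binary classification, written with plain
# matrix algebra (no multi-hidden-layer network package is available to the
# package). Architecture used by the registry: four hidden layers of sizes
# 100, 150, 100, 50; logistic, ReLU or tanh hidden activation; sigmoid
# output trained on binary cross-entropy with full-batch Adam, at most
# `max_iter` epochs and tolerance-based early stopping (stop when the loss
# has not improved by more than `tol` for `n_iter_no_change` epochs).

mlp_activation <- function(name) {
  switch(name,
    logistic = list(
      f = function(z) 1 / (1 + exp(-z)),
      df = function(a) a * (1 - a)
    ),
    relu = list(
      f = function(z) pmax(z, 0),
      df = function(a) (a > 0) * 1
    ),
    tanh = list(
      f = tanh,
      df = function(a) 1 - a^2
    ),
    stop(sprintf("unknown MLP activation '%s'", name), call. = FALSE)
  )
}

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1]
    r <- sqrt(6 / (fan_in + fan_out)) # Glorot uniform
    list(
      W = matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out),
      b = rep(0, fan_out)
    )
  })
}

mlp_forward <- function(params, X, act) {
  L <- length(params)
  a <- vector("list", L + 1)
  a[[1]] <- X
  for (l in seq_len(L)) {
    z <- a[[l]] %*% params[[l]]$W +
      matrix(params[[l]]$b, nrow(X), ncol(params[[l]]$W), byrow = TRUE)
    a[[l + 1]] <- if (l < L) act$f(z) else 1 / (1 + exp(-z))
  }
  a
}

fit_mlp <- function(X, y, hidden = c(100, 150, 100, 50),
                    activation = "relu", max_iter = 1000,
                    learning_rate = 1e-3, tol = 1e-4,
                    n_iter_no_change = 10) {
  act <- mlp_activation(activation)
  sizes <- c(ncol(X), hidden, 1)
  params <- mlp_init(sizes)
  L <- length(params)
  n <- nrow(X)
  yv <- matrix(as.numeric(y), n, 1)

  # Adam state
  m_w <- lapply(params, function(p) p$W * 0)
  v_w <- lapply(params, function(p) p$W * 0)
  m_b <- lapply(params, function(p) p$b * 0)
  v_b <- lapply(params, function(p) p$b * 0)
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8

  best_loss <- Inf
  stall <- 0
  n_iter <- 0
  for (it in seq_len(max_iter)) {
    a <- mlp_forward(params, X, act)
    p_hat <- pmin(pmax(a[[L + 1]], 1e-12), 1 - 1e-12)
    loss <- -mean(yv * log(p_hat) + (1 - yv) * log(1 - p_hat))
    if (!is.finite(loss)) break
    n_iter <- it

    # backprop
    delta <- (a[[L + 1]] - yv) / n
    for (l in rev(seq_len(L))) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      # clip exploding gradients (unscaled inputs can saturate ReLU nets)
      gn <- sqrt(sum(gW^2) + sum(gb^2))
      if (is.finite(gn) && gn > 10) {
        gW <- gW * (10 / gn)
        gb <- gb * (10 / gn)
      }
      if (l > 1) {
        delta <- (delta %*% t(params[[l]]$W)) * act$df(a[[l]])
      }
      m_w[[l]] <- beta1 * m_w[[l]] + (1 - beta1) * gW
      v_w[[l]] <- beta2 * v_w[[l]] + (1 - beta2) * gW^2
      m_b[[l]] <- beta1 * m_b[[l]] + (1 - beta1) * gb
      v_b[[l]] <- beta2 * v_b[[l]] + (1 - beta2) * gb^2
      mw_hat <- m_w[[l]] / (1 - beta1^it)
      vw_hat <- v_w[[l]] / (1 - beta2^it)
      mb_hat <- m_b[[l]] / (1 - beta1^it)
      vb_hat <- v_b[[l]] / (1 - beta2^it)
      params[[l]]$W <- params[[l]]$W -
        learning_rate * mw_hat / (sqrt(vw_hat) + eps)
      params[[l]]$b <- params[[l]]$b -
        learning_rate * mb_hat / (sqrt(vb_hat) + eps)
    }

    if (loss > best_loss - tol) {
      stall <- stall + 1
      if (stall >= n_iter_no_change) break
    } else {
      stall <- 0
    }
    best_loss <- min(best_loss, loss)
  }
  list(params = params, activation = activation, n_iter = n_iter)
}

mlp_prob <- function(model, X) {
  act <- mlp_activation(model$activation)
  a <- mlp_forward(model$params, X, act)
  as.numeric(a[[length(a)]])
}
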