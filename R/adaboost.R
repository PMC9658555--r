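# Discrete AdaBoost (SAMME) over depth-1 rpart stumps.
#
# Boosting is written out here because no boosting-classifier package is
# available to the package; the base learner is delegated to rpart. With two
# classes SAMME reduces to classic discrete AdaBoost: each round fits a
# stump under the current instance weights, the stump gets a log-odds vote
# from its weighted error, and misclassified instances are up-weighted.

fit_adaboost <- function(X, y, n_trees = 50) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
  stumps <- vector("list", n_trees)
  alphas <- numeric(n_trees)
  used <- 0
  for (m in seq_len(n_trees)) {
    fit <- rpart::rpart(
      .y ~ .,
      data = df, weights = w, method = "class",
      control = rpart::rpart.control(
        maxdepth = 1, cp = -1, minsplit = 2,
        minbucket = 1, xval = 0, maxsurrogate = 0,
        maxcompete = 0
      )
    )
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    if (err >= 0.5) break # stump no better than chance: stop boosting
    if (err <= 0) {
      # perfect stump: give it a large but finite vote and stop
      used <- m
      stumps[[m]] <- fit
      alphas[m] <- log((1 - 1e-10) / 1e-10) / 2
      break
    }
    alpha <- log((1 - err) / err) / 2
    stumps[[m]] <- fit
    alphas[m] <- alpha
    used <- m
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)])
}

# Normalized weighted-vote margin in [-1, 1]; monotone score for ROC.
adaboost_margin <- function(model, X) {
  df <- as.data.frame(X)
  if (length(model$stumps) == 0) {
    return(rep(0, nrow(X)))
  }
  f <- numeric(nrow(X))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(
      predict(model$stumps[[m]], df, type = "class")
    ))
    f <- f + model$alphas[m] * ifelse(pred == 1, 1, -1)
  }
  f / sum(model$alphas)
}
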