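# The 14 classifier configurations behind one fit/score/predict contract.
# Learners are delegated: glmnet (ridge logistic regression), class::knn,
# rpart (decision tree), e1071 (Gaussian naive Bayes, libsvm), randomForest.
# AdaBoost (adaboost.R) and the 4-hidden-layer MLP (mlp.R) are implemented
# in-package because no installed package provides them.

#' Registry of the 14 classifier configurations
#'
#' Returns the classifier suite in the stable order used by all result
#' tables: logistic regression (ridge penalty, max 1000 iterations),
#' AdaBoost (50 stumps), KNN (k-d tree, k = 5), decision tree (unlimited
#' depth), Gaussian naive Bayes, SVM with rbf / sigmoid / polynomial
#' (degree 3, 5, 10) kernels, random forest (100 trees), and MLPs with four
#' hidden layers (100, 150, 100, 50) and logistic / ReLU / tanh activation
#' trained for at most 1000 iterations.
#'
#' @param seed seed stored in every spec (fit-time randomness).
#' @return list of `classifier_spec` objects, length 14.
#' @export
#' @examples
#' length(classifier_registry())
#' classifier_registry()[[11]]$hyperparameters$n_trees
classifier_registry <- function(seed = 1L) {
  specs <- list(
    list(
      id = "LR", label = "Logistic Regression",
      hyperparameters = list(max_iter = 1000, penalty = "l2")
    ),
    list(
      id = "AdaBoost", label = "AdaBoost",
      hyperparameters = list(n_trees = 50)
    ),
    list(
      id = "KNN", label = "KNN",
      hyperparameters = list(k = 5, algorithm = "kd_tree")
    ),
    list(
      id = "DecisionTree", label = "Decision Tree",
      hyperparameters = list(max_depth = Inf)
    ),
    list(
      id = "GaussianNB", label = "Gaussian",
      hyperparameters = list()
    ),
    list(
      id = "SVM-rbf", label = "SVM kernel = rbf",
      hyperparameters = list(kernel = "radial", max_iter = 1000)
    ),
    list(
      id = "SVM-sigmoid", label = "SVM kernel = sigmoid",
      hyperparameters = list(kernel = "sigmoid", max_iter = 1000)
    ),
    list(
      id = "SVM-poly3", label = "SVM kernel = poly, deg = 3",
      hyperparameters = list(kernel = "polynomial", degree = 3,
        max_iter = 1000
      )
    ),
    list(
      id = "SVM-poly5", label = "SVM kernel = poly, deg = 5",
      hyperparameters = list(kernel = "polynomial", degree = 5,
        max_iter = 1000
      )
    ),
    list(
      id = "SVM-poly10", label = "SVM kernel = poly, deg = 10",
      hyperparameters = list(kernel = "polynomial", degree = 10,
        max_iter = 1000
      )
    ),
    list(
      id = "RandomForest", label = "Random Forest",
      hyperparameters = list(n_trees = 100)
    ),
    list(
      id = "MLP-logistic", label = "MLP activation = logistic",
      hyperparameters = list(
        hidden = c(100, 150, 100, 50),
        activation = "logistic", max_iter = 1000
      )
    ),
    list(
      id = "MLP-relu", label = "MLP activation = ReLU",
      hyperparameters = list(
        hidden = c(100, 150, 100, 50),
        activation = "relu", max_iter = 1000
      )
    ),
    list(
      id = "MLP-tanh", label = "MLP activation = tanh",
      hyperparameters = list(
        hidden = c(100, 150, 100, 50),
        activation = "tanh", max_iter = 1000
      )
    )
  )
  lapply(specs, function(s) {
    s$seed <- as.integer(seed)
    structure(s, class = "classifier_spec")
  })
}

#' Look up one classifier spec by id or label
#'
#' @param name a spec `id` (e.g. `"RandomForest"`) or table `label`
#'   (e.g. `"Random Forest"`).
#' @param seed seed stored in the spec.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(name, seed = 1L) {
  reg <- classifier_registry(seed)
  ids <- vapply(reg, `[[`, "", "id")
  labels <- vapply(reg, `[[`, "", "label")
  i <- match(name, ids)
  if (is.na(i)) i <- match(name, labels)
  if (is.na(i)) {
    stop(sprintf(
      "unknown classifier '%s'; known ids: %s",
      name, paste(ids, collapse = ", ")
    ), call. = FALSE)
  }
  reg[[i]]
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
    vapply(x$hyperparameters, function(v) {
      paste(format(v), collapse = ",")
    }, ""),
    sep = "=", collapse = "; "
  )
  cat(sprintf("<classifier_spec> %s (%s)%s\n", x$id, x$label,
    if (nzchar(hp)) paste0(": ", hp) else ""
  ))
  invisible(x)
}

# Seeded undersampling of the majority class to a 1:1 balance.
undersample_majority <- function(y) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (length(pos) == length(neg)) {
    return(sort(c(pos, neg)))
  }
  maj <- if (length(pos) > length(neg)) pos else neg
  mino <- if (length(pos) > length(neg)) neg else pos
  sort(c(mino, sample(maj, length(mino))))
}

#' Fit one classifier configuration
#'
#' Uniform training entry point for the registry. Optionally undersamples
#' the majority class to a 1:1 balance (seeded; default on, training rows
#' only) and optionally standardizes features with training-set statistics
#' (default off). Deterministic given `(spec$seed, seed)`.
#'
#' @param spec a `classifier_spec` (see [classifier_registry()]).
#' @param X numeric feature matrix (rows = registrations).
#' @param y binary 0/1 labels, one per row; both classes must be present.
#' @param standardize center/scale features using training statistics.
#' @param balance undersample the majority class before fitting.
#' @param seed overrides `spec$seed` when given.
#' @return object of class `trained_model` with the fitted state and
#'   training metadata (`n_total`, `n_train`, class counts, flags).
#' @export
fit_classifier <- function(spec, X, y, standardize = FALSE, balance = TRUE,
                           seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  }
  y <- as.integer(y)
  if (nrow(X) != length(y)) {
    stop("X rows and y length differ", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite feature value at row %d", bad[1, 1]),
      call. = FALSE
    )
  }
  if (is.null(seed)) seed <- spec$seed

  fitted <- with_substream(seed, {
    idx <- if (balance) undersample_majority(y) else seq_along(y)
    Xt <- X[idx, , drop = FALSE]
    yt <- y[idx]

    center <- rep(0, ncol(X))
    scale_ <- rep(1, ncol(X))
    if (standardize) {
      center <- colMeans(Xt)
      scale_ <- apply(Xt, 2, stats::sd)
      scale_[scale_ == 0 | !is.finite(scale_)] <- 1
      Xt <- sweep(sweep(Xt, 2, center), 2, scale_, "/")
    }

    state <- fit_learner(spec, Xt, yt)
    list(
      state = state, idx = idx, yt = yt,
      center = center, scale = scale_
    )
  })

  structure(
    list(
      spec = spec,
      state = fitted$state,
      center = fitted$center,
      scale = fitted$scale,
      standardize = standardize,
      metadata = list(
        n_total = length(y),
        n_train = length(fitted$idx),
        class_counts_total = c(neg = sum(y == 0), pos = sum(y == 1)),
        class_counts_train = c(
          neg = sum(fitted$yt == 0),
          pos = sum(fitted$yt == 1)
        ),
        balanced = balance,
        standardized = standardize,
        n_features = ncol(X),
        seed = seed
      )
    ),
    class = "trained_model"
  )
}

fit_learner <- function(spec, X, y) {
  hp <- spec$hyperparameters
  switch(spec$id,
    "LR" = {
      fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)),
        family = "binomial", alpha = 0,
        lambda = 1 / nrow(X), standardize = FALSE,
        maxit = hp$max_iter
      )
      list(kind = "glmnet", fit = fit)
    },
    "AdaBoost" = list(
      kind = "adaboost",
      fit = fit_adaboost(X, y, n_trees = hp$n_trees)
    ),
    "KNN" = list(kind = "knn", X = X, y = y, k = hp$k),
    "DecisionTree" = {
      df <- data.frame(
        .y = factor(y, levels = c(0, 1)), X,
        check.names = FALSE
      )
      fit <- rpart::rpart(
        .y ~ .,
        data = df, method = "class",
        control = rpart::rpart.control(
          cp = 0, minsplit = 2, minbucket = 1,
          xval = 0, maxdepth = 30,
          maxsurrogate = 0, maxcompete = 0
        )
      )
      list(kind = "rpart", fit = fit)
    },
    "GaussianNB" = {
      fit <- e1071::naiveBayes(
        x = as.data.frame(X),
        y = factor(y, levels = c(0, 1))
      )
      # guard zero-variance features: dnorm with sd 0 is degenerate
      fit$tables <- lapply(fit$tables, function(tab) {
        tab[, 2][tab[, 2] < 1e-9 | !is.finite(tab[, 2])] <- 1e-9
        tab
      })
      list(kind = "nb", fit = fit)
    },
    "RandomForest" = {
      fit <- randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = hp$n_trees
      )
      list(kind = "rf", fit = fit)
    },
    "MLP-logistic" = ,
    "MLP-relu" = ,
    "MLP-tanh" = list(
      kind = "mlp",
      fit = fit_mlp(X, y,
        hidden = hp$hidden, activation = hp$activation,
        max_iter = hp$max_iter
      )
    ),
    {
      if (!startsWith(spec$id, "SVM")) {
        stop(sprintf("unknown classifier id '%s'", spec$id), call. = FALSE)
      }
      v <- stats::var(as.vector(X))
      gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
      fit <- e1071::svm(
        x = X, y = factor(y, levels = c(0, 1)),
        type = "C-classification",
        kernel = hp$kernel,
        degree = if (is.null(hp$degree)) 3 else hp$degree,
        gamma = gamma, coef0 = 0, cost = 1,
        scale = FALSE, fitted = FALSE
      )
      list(kind = "svm", fit = fit)
    }
  )
}

#' Score and predict with a trained model
#'
#' `score_classifier` returns a continuous score per row (higher = more
#' likely exercise): a class-1 probability for the probabilistic learners,
#' the positive vote fraction for KNN and the random forest, the normalized
#' weighted-vote margin mapped through the logistic function for AdaBoost,
#' and the decision value mapped through the logistic function for the
#' SVMs. `predict_classifier` thresholds the score at the model's operating
#' point (0.5 on this scale for every learner), so predictions and scores
#' are consistent by construction.
#'
#' @param model a `trained_model` from [fit_classifier()].
#' @param X feature matrix with the training width.
#' @param threshold operating point on the score scale.
#' @return `score_classifier`: numeric vector in (0, 1);
#'   `predict_classifier`: integer 0/1 vector.
#' @export
score_classifier <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  }
  if (ncol(X) != model$metadata$n_features) {
    stop(sprintf(
      "feature width %d differs from training width %d",
      ncol(X), model$metadata$n_features
    ), call. = FALSE)
  }
  if (model$standardize) {
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  }
  st <- model$state
  switch(st$kind,
    glmnet = as.numeric(
      stats::predict(st$fit, X, type = "response")[, 1]
    ),
    adaboost = stats::plogis(2 * adaboost_margin(st$fit, X)),
    knn = {
      res <- class::knn(st$X, X, factor(st$y, levels = c(0, 1)),
        k = st$k, prob = TRUE
      )
      pr <- attr(res, "prob")
      ifelse(res == "1", pr, 1 - pr)
    },
    rpart = as.numeric(
      stats::predict(st$fit, as.data.frame(X), type = "prob")[, "1"]
    ),
    nb = as.numeric(
      stats::predict(st$fit, as.data.frame(X), type = "raw")[, "1"]
    ),
    rf = as.numeric(
      stats::predict(st$fit, X, type = "prob")[, "1"]
    ),
    mlp = mlp_prob(st$fit, X),
    svm = {
      pred <- stats::predict(st$fit, X, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      s <- if (identical(first, "1")) dv[, 1] else -dv[, 1]
      stats::plogis(as.numeric(s))
    },
    stop("unknown fitted state", call. = FALSE)
  )
}

#' @rdname score_classifier
#' @export
predict_classifier <- function(model, X, threshold = 0.5) {
  as.integer(score_classifier(model, X) >= threshold)
}

#' @export
print.trained_model <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<trained_model> %s: %d/%d rows used (%s), %d features%s%s\n",
    x$spec$label, md$n_train, md$n_total,
    paste(names(md$class_counts_train), md$class_counts_train,
      sep = "=", collapse = ", "
    ),
    md$n_features,
    if (md$balanced) ", balanced" else "",
    if (md$standardized) ", standardized" else ""
  ))
  invisible(x)
}
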