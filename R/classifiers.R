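#' Base-classifier specification
#'
#' Describes one supervised base classifier for the ensemble. Four kinds
#' are available; hyperparameter defaults are the tuned operating points
#' used for the indoor-pollutant E-nose setup, and every one can be
#' overridden:
#'
#' * `svm_rbf` — support vector machine with RBF kernel (via e1071);
#'   `kernel_width` is the kernel coefficient gamma multiplying the
#'   squared distance (default 0.2749), `penalty` the soft-margin cost C
#'   (default 0.4848). Multi-class by one-vs-one majority.
#' * `plsda` — partial least squares discriminant analysis (via mixOmics):
#'   one-hot response regression, class = argmax of the predicted
#'   response; `latent_variables` (default 5) is capped at the feature
#'   dimension at fit time.
#' * `rbf_network` — Gaussian radial-basis-function network with greedy
#'   forward center selection until the residual sum of squares of the
#'   one-hot output layer falls below `goal_mse` (default 0.4329; the
#'   classical error-goal stopping rule of incremental RBF design) or
#'   `max_neurons` centers are placed; `spread` (default 0.0176) is the
#'   Gaussian width on standardized features.
#' * `nearest_centroid` — class-mean centroids, nearest by Euclidean
#'   distance; fast and fully deterministic, handy for tests.
#'
#' `svm_rbf` and `rbf_network` standardize features to zero mean / unit
#' variance using statistics of their own training pool (RBF kernels at
#' these widths are scale-sensitive); zero-variance features get unit
#' scale instead of failing.
#'
#' @param kind one of `"svm_rbf"`, `"plsda"`, `"rbf_network"`,
#'   `"nearest_centroid"`.
#' @param ... kind-specific hyperparameters (see above).
#' @param seed integer seed stored with the spec.
#' @return a `classifier_spec` object.
#' @examples
#' classifier_spec("svm_rbf")
#' classifier_spec("plsda", latent_variables = 3)
#' @export
classifier_spec <- function(kind = c("svm_rbf", "plsda", "rbf_network",
                                     "nearest_centroid"),
                            ..., seed = 0L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm_rbf = list(kernel_width = 0.2749, penalty = 0.4848),
    plsda = list(latent_variables = 5L),
    rbf_network = list(goal_mse = 0.4329, spread = 0.0176, max_neurons = 60L),
    nearest_centroid = list()
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown hyperparameter(s) for %s: %s", kind,
                  paste(unknown, collapse = ", ")))
  }
  hp <- utils::modifyList(defaults, override)
  num <- unlist(hp[vapply(hp, is.numeric, logical(1))])
  if (any(num <= 0)) abort("hyperparameters must be positive")
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = " = ", collapse = ", ")
  cat(sprintf("<classifier_spec> %s(%s), seed %d\n", x$kind, hp, x$seed))
  invisible(x)
}

fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1  # zero-variance guard
  list(center = center, scale = scale)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Fit a base classifier
#'
#' Fits the classifier described by `spec` on a labeled feature table.
#' Prediction is a pure function of the fitted state: the same spec, data
#' and seed give identical predictions.
#'
#' @param data labeled feature table (no `NA` labels, at least 2 classes).
#' @param spec a [classifier_spec()].
#' @return an object of class `mtrain_classifier` with a [predict][
#'   predict.mtrain_classifier] method returning character labels.
#' @export
fit_classifier <- function(data, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  validate_feature_table(data)
  if (nrow(data) == 0) abort("empty training set")
  if (any(is.na(data$label))) abort("training set must be fully labeled")
  label_set <- label_order(data$label)
  if (length(label_set) < 2) abort("training set has a single class")
  X <- feature_matrix(data)
  y <- factor(data$label, levels = label_set)
  hp <- spec$hyperparameters
  scaler <- NULL
  fitted <- switch(spec$kind,
    svm_rbf = {
      scaler <- fit_scaler(X)
      Xs <- apply_scaler(X, scaler)
      with_seed(spec$seed, e1071::svm(
        x = Xs, y = y, kernel = "radial",
        gamma = hp$kernel_width, cost = hp$penalty, scale = FALSE
      ))
    },
    plsda = {
      if (!requireNamespace("mixOmics", quietly = TRUE)) {
        abort("the plsda classifier needs the mixOmics package")
      }
      ncomp <- min(hp$latent_variables, ncol(X),
                   length(label_set) * ncol(X))
      if (hp$latent_variables > ncol(X)) {
        inform(sprintf("plsda: latent_variables capped at %d (feature dimension)",
                       ncomp))
      }
      with_seed(spec$seed,
                mixOmics::plsda(X, y, ncomp = ncomp))
    },
    rbf_network = {
      scaler <- fit_scaler(X)
      fit_rbf_network(apply_scaler(X, scaler), y,
                      goal_mse = hp$goal_mse, spread = hp$spread,
                      max_neurons = hp$max_neurons)
    },
    nearest_centroid = {
      cent <- do.call(rbind, lapply(label_set, function(cl) {
        colMeans(X[y == cl, , drop = FALSE])
      }))
      rownames(cent) <- label_set
      cent
    }
  )
  structure(list(kind = spec$kind, spec = spec, fitted = fitted,
                 label_set = label_set, features = feature_cols(data),
                 scaler = scaler),
            class = "mtrain_classifier")
}

# Predictor feature matrix aligned to fit-time columns.
align_features <- function(object, newdata) {
  cols <- object$features
  have <- feature_cols(newdata)
  if (!setequal(have, cols) || length(have) != length(cols)) {
    abort(sprintf("feature mismatch: model expects {%s}, data has {%s}",
                  paste(cols, collapse = ","), paste(have, collapse = ",")))
  }
  m <- as.matrix(newdata[cols])
  storage.mode(m) <- "double"
  m
}

#' Predict class labels
#'
#' @param object a fitted [fit_classifier()] model.
#' @param newdata feature table tibble; feature columns must match the
#'   fit-time columns.
#' @param ... unused.
#' @return character vector of labels, one per row, each from the
#'   fit-time label set; argmax ties are broken by the lowest label in
#'   the fixed (sorted) label ordering.
#' @export
predict.mtrain_classifier <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) return(character(0))
  if (object$kind == "fixed") {
    return(unname(object$fitted[newdata$sample_id]))
  }
  X <- align_features(object, newdata)
  lv <- object$label_set
  switch(object$kind,
    svm_rbf = as.character(predict(object$fitted,
                                   apply_scaler(X, object$scaler))),
    plsda = {
      pp <- predict(object$fitted, X)$predict
      scores <- matrix(pp[, , dim(pp)[3]], nrow = dim(pp)[1],
                       dimnames = list(NULL, dimnames(pp)[[2]]))
      lv[max.col(scores[, lv, drop = FALSE], ties.method = "first")]
    },
    rbf_network = predict_rbf_network(object$fitted,
                                      apply_scaler(X, object$scaler), lv),
    nearest_centroid = {
      d2 <- outer(rowSums(X^2), rep(1, nrow(object$fitted))) -
        2 * X %*% t(object$fitted) +
        outer(rep(1, nrow(X)), rowSums(object$fitted^2))
      lv[apply(d2, 1, which.min)]  # which.min: first (lowest label) on ties
    }
  )
}

# Test-only stand-in classifier with scripted predictions keyed on
# sample_id; lets vote-combination logic be exercised with exact,
# hand-written vote patterns.
fixed_classifier <- function(lookup, label_set = label_order(lookup)) {
  structure(list(kind = "fixed", fitted = lookup, label_set = label_set,
                 features = NULL, scaler = NULL),
            class = "mtrain_classifier")
}

# --- Gaussian RBF network ------------------------------------------------
# Greedy forward selection of training points as centers: at each step the
# candidate whose kernel column best explains the current one-hot residual
# (largest projected energy) is added and the output layer refit by least
# squares; stops when the residual sum of squares reaches the error goal
# or at max_neurons. Output layer includes a bias.
fit_rbf_network <- function(X, y, goal_mse, spread, max_neurons) {
  n <- nrow(X)
  lv <- levels(y)
  Y <- outer(as.character(y), lv, "==") * 1
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * spread^2))
  max_neurons <- min(max_neurons, n)
  # ridge-stabilized least squares: the kernel design is near-singular at
  # small spreads, so a tiny ridge keeps the solve rank-robust
  ls_fit <- function(design) {
    A <- crossprod(design) + 1e-8 * diag(ncol(design))
    solve(A, crossprod(design, Y))
  }
  selected <- integer(0)
  design <- matrix(1, n, 1)
  W <- ls_fit(design)
  resid <- Y - design %*% W
  sse <- sum(resid^2)
  while (sse > goal_mse && length(selected) < max_neurons) {
    cand <- setdiff(seq_len(n), selected)
    score <- vapply(cand, function(j) {
      kj <- K[, j]
      sum((crossprod(resid, kj))^2) / sum(kj^2)
    }, numeric(1))
    best <- cand[which.max(score)]
    selected <- c(selected, best)
    design <- cbind(1, K[, selected, drop = FALSE])
    W <- ls_fit(design)
    resid <- Y - design %*% W
    new_sse <- sum(resid^2)
    if (new_sse >= sse - 1e-12) {  # no progress
      break
    }
    sse <- new_sse
  }
  design <- cbind(1, K[, selected, drop = FALSE])
  W <- ls_fit(design)
  list(centers = X[selected, , drop = FALSE], weights = W, spread = spread,
       sse = sum((Y - design %*% W)^2))
}

predict_rbf_network <- function(net, X, label_set) {
  if (nrow(net$centers) == 0) {
    Phi <- matrix(1, nrow(X), 1)
  } else {
    d2 <- outer(rowSums(X^2), rep(1, nrow(net$centers))) -
      2 * X %*% t(net$centers) +
      outer(rep(1, nrow(X)), rowSums(net$centers^2))
    Phi <- cbind(1, exp(-pmax(d2, 0) / (2 * net$spread^2)))
  }
  scores <- Phi %*% net$weights
  label_set[max.col(scores, ties.method = "first")]
}
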