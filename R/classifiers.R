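# Thin fit/predict wrappers over established classifiers, each with a small
# hyperparameter grid appropriate for three features. Features are assumed
# already standardized by the CV harness.

classifier_grid <- function(tag, x) {
  switch(tag,
    lsvm = lapply(c(0.1, 1, 10), function(C) list(C = C)),
    rsvm = {
      med <- stats::median(stats::dist(x)^2)
      g0 <- 1 / max(med, 1e-8)
      unlist(lapply(c(0.1, 1, 10), function(C) {
        lapply(g0 * c(0.1, 1, 10), function(g) list(C = C, gamma = g))
      }), recursive = FALSE)
    },
    knn = lapply(c(3L, 5L, 7L, 9L), function(k) list(k = k)),
    ann = lapply(c(3L, 5L, 8L), function(size) list(size = size)),
    abort_field("classifier_tag", "must be one of lsvm, rsvm, knn, ann")
  )
}

fit_classifier <- function(tag, x, y, params) {
  switch(tag,
    lsvm = e1071::svm(x, y, kernel = "linear", cost = params$C, scale = FALSE),
    rsvm = e1071::svm(x, y, kernel = "radial", cost = params$C,
                      gamma = params$gamma, scale = FALSE),
    knn = list(train = x, cl = y, k = params$k),
    ann = nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2L, drop = FALSE],
                     size = params$size, decay = 0.1, maxit = 200,
                     trace = FALSE, entropy = TRUE)
  )
}

predict_classifier <- function(tag, fit, newx, levels_y) {
  switch(tag,
    lsvm = ,
    rsvm = stats::predict(fit, newx),
    knn = {
      k <- min(fit$k, nrow(fit$train))
      class::knn(fit$train, newx, fit$cl, k = k)
    },
    ann = factor(levels_y[1L + (stats::predict(fit, newx) > 0.5)],
                 levels = levels_y)
  )
}

# Inner grid search: stratified 75/25 holdout of the training fold; the best
# grid point (ties -> first) is refit on the whole training fold.
tune_and_fit <- function(tag, x, y, inner_seed) {
  grid <- classifier_grid(tag, x)
  if (length(grid) > 1L) {
    hold <- with_seed(inner_seed, stratified_holdout(y, prop = 0.25))
    acc <- vapply(grid, function(params) {
      fit <- fit_classifier(tag, x[-hold, , drop = FALSE], y[-hold], params)
      pred <- predict_classifier(tag, fit, x[hold, , drop = FALSE], levels(y))
      mean(pred == y[hold])
    }, numeric(1))
    params <- grid[[which.max(acc)]]
  } else {
    params <- grid[[1L]]
  }
  fit_classifier(tag, x, y, params)
}

stratified_holdout <- function(y, prop) {
  unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    n_hold <- max(1L, round(prop * length(idx)))
    sample(idx, n_hold)
  }), use.names = FALSE)
}

# Stratified fold assignment: within each class, shuffle then deal into
# folds round-robin, so every fold sees both classes when counts allow.
stratified_folds <- function(y, folds) {
  assignment <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}
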