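# Cohort-level assembly of graph features, the repeated stratified k-fold
# classification harness, and the full method x metric x PT sweep.

distance_for_metric <- function(A, metric, max_lag = 3L) {
  switch(metric,
    cross_correlation = cross_correlation_distance(A, max_lag = max_lag),
    euclidean = euclidean_distance(A),
    abort_field("metric", "must be 'cross_correlation' or 'euclidean'")
  )
}

# Embedded (or raw) distance matrix for one subject under one
# configuration. `params` may carry k (isomap/lle), sigma & t (dmaps),
# gamma (kpca), p ("auto" -> eigengap on a probe embedding).
subject_config_distance <- function(D, method, params) {
  if (method == "none") return(D)
  m <- nrow(D)
  pick_p <- function(emb) {
    p <- params$p %||% "auto"
    if (identical(p, "auto")) select_dimension(emb, max_p = min(5L, m - 1L)) else check_count(p, "p")
  }
  emb <- switch(method,
    mds = {
      probe <- mds_embed(D, p = 1L)
      mds_embed(D, p = pick_p(probe))
    },
    isomap = {
      k <- params$k %||% 5L
      probe <- isomap_embed(D, k = k, p = 1L)
      isomap_embed(D, k = k, p = pick_p(probe))
    },
    dmaps = {
      sigma <- params$sigma %||% select_sigma(D)$sigma
      t <- params$t %||% 1L
      probe <- diffusion_embed(D, sigma, t = t, p = 1L)
      diffusion_embed(D, sigma, t = t, p = pick_p(probe))
    },
    kpca = {
      gamma <- params$gamma %||% select_gamma(D)
      probe <- kpca_embed(D, gamma, p = 1L)
      kpca_embed(D, gamma, p = pick_p(probe))
    },
    lle = {
      k <- params$k %||% 7L
      probe <- lle_embed(D, k = k, p = 1L)
      lle_embed(D, k = k, p = pick_p(probe))
    },
    abort_field("method", "unknown embedding method")
  )
  embedded_distance_matrix(emb)
}

#' Assemble per-subject graph features under one configuration
#'
#' Runs the full per-subject pipeline -- distance metric, optional
#' embedding (`method = "none"` keeps the raw metric matrix, the
#' conventional baseline), proportional thresholding, largest component,
#' global measures -- and stacks the results into a feature table. A
#' subject whose configuration fails (e.g. a disconnected neighbor graph)
#' is excluded with the reason recorded; if more than 20% of subjects drop
#' out the configuration is unusable and an error is raised.
#'
#' @param cohort Tibble with columns `subject_id`, `group` (factor, second
#'   level = positive/patient-like class) and `timecourses` (list of
#'   component x time matrices), as from [generate_cohort()] or
#'   [read_cohort()].
#' @param metric `"cross_correlation"` or `"euclidean"`.
#' @param method One of `"none"`, `"mds"`, `"isomap"`, `"dmaps"`,
#'   `"kpca"`, `"lle"`.
#' @param params Named list of method parameters (`k`, `sigma`, `t`,
#'   `gamma`, `p`); `p = "auto"` (default) uses the eigengap rule.
#' @param pt Proportional threshold.
#' @param max_lag Maximum lag for the cross-correlation metric.
#' @return A tibble with columns `subject_id`, `group`, `L`, `Cg`, `Mk`
#'   (excluded subjects dropped); excluded subjects are recorded in
#'   `attr(, "excluded")`.
#' @export
assemble_features <- function(cohort, metric = "cross_correlation",
                              method = "none", params = list(),
                              pt = 0.3, max_lag = 3L) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    res <- tryCatch({
      D <- distance_for_metric(cohort$timecourses[[i]], metric, max_lag)
      DY <- subject_config_distance(D, method, params)
      feats <- graph_features(DY, pt)
      tibble::tibble(
        subject_id = cohort$subject_id[i], group = cohort$group[i],
        L = feats$L, Cg = feats$Cg, Mk = feats$Mk
      )
    }, error = function(e) {
      tibble::tibble(
        subject_id = cohort$subject_id[i], group = cohort$group[i],
        L = NA_real_, Cg = NA_real_, Mk = NA_real_,
        reason = conditionMessage(e)
      )
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  excluded <- dplyr::filter(out, is.na(.data$L))
  out <- dplyr::select(dplyr::filter(out, !is.na(.data$L)), -dplyr::any_of("reason"))
  if (nrow(excluded) > 0.2 * nrow(cohort)) {
    rlang::abort(sprintf(
      "%d of %d subjects failed under this configuration (> 20%%); first reason: %s",
      nrow(excluded), nrow(cohort), excluded$reason[1L]
    ), class = "fcnembed_config_error")
  }
  attr(out, "excluded") <- excluded
  out
}

#' Sensitivity and specificity from a confusion matrix
#'
#' @param cm Named list or vector with elements `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `c(sensitivity, specificity)`;
#'   `TPR = TP/(TP + FN)`, `TNR = TN/(TN + FP)`. A zero denominator gives
#'   `NaN`.
#' @export
confusion_stats <- function(cm) {
  cm <- as.list(cm)
  sens <- cm$TP / (cm$TP + cm$FN)
  spec <- cm$TN / (cm$TN + cm$FP)
  c(sensitivity = sens, specificity = spec)
}

#' Repeated stratified k-fold cross-validation over graph features
#'
#' Stratified folds are drawn fresh each repeat; within every training
#' fold the three features are standardized by the training fold's own
#' mean and SD (applied to the validation fold), hyperparameters are tuned
#' by an inner stratified holdout grid search, and the tuned model is
#' refit on the full training fold. Accuracy per repeat pools the
#' validation predictions of its folds; the confusion matrix is averaged
#' over all repeats.
#'
#' @param ft Feature table from [assemble_features()] (columns `group`,
#'   `L`, `Cg`, `Mk`; the second factor level of `group` is the positive
#'   class).
#' @param classifier_tag `"lsvm"`, `"rsvm"`, `"knn"` or `"ann"`.
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (the study uses 100).
#' @param seed Integer seed controlling fold draws and tuning splits.
#' @return An object of class `"fcn_cv"`: `mean_accuracy` and
#'   `sd_accuracy` in percent (mean/SD over the per-repeat accuracies),
#'   `accuracies` (per repeat, percent), `confusion` (average counts per
#'   repeat), `sensitivity`, `specificity` (percent), plus the
#'   configuration fields.
#' @examples
#' ft <- tibble::tibble(
#'   group = factor(rep(c("a", "b"), each = 20)),
#'   L = c(rnorm(20, 1.2, .05), rnorm(20, 1.8, .05)),
#'   Cg = stats::runif(40, .4, .6), Mk = stats::runif(40, 5, 7)
#' )
#' cv <- repeated_kfold_cv(ft, "knn", folds = 5, repeats = 3, seed = 1)
#' cv$mean_accuracy
#' @export
repeated_kfold_cv <- function(ft, classifier_tag = "rsvm", folds = 10L,
                              repeats = 100L, seed = 1L) {
  folds <- check_count(folds, "folds", min = 2L)
  repeats <- check_count(repeats, "repeats", min = 1L)
  y <- droplevels(factor(ft$group))
  if (nlevels(y) != 2L) abort_field("ft", "needs exactly two classes in `group`")
  if (min(table(y)) < folds) abort_field("folds", "each class must have at least `folds` members")
  x <- as.matrix(ft[, c("L", "Cg", "Mk")])
  if (any(!is.finite(x))) abort_field("ft", "features must be finite")
  n <- nrow(x)
  pos <- levels(y)[2L]
  seeds <- split_seed(seed, repeats)
  per_repeat <- purrr::map(seq_len(repeats), function(r) {
    with_seed(seeds[r], {
      fold_of <- stratified_folds(y, folds)
      pred <- factor(rep(NA_character_, n), levels = levels(y))
      for (f in seq_len(folds)) {
        test_idx <- which(fold_of == f)
        train_idx <- which(fold_of != f)
        mu <- colMeans(x[train_idx, , drop = FALSE])
        sd_ <- apply(x[train_idx, , drop = FALSE], 2L, stats::sd)
        sd_[sd_ == 0] <- 1
        xtr <- scale(x[train_idx, , drop = FALSE], center = mu, scale = sd_)
        xte <- scale(x[test_idx, , drop = FALSE], center = mu, scale = sd_)
        fit <- tune_and_fit(classifier_tag, xtr, y[train_idx],
                            inner_seed = sample.int(.Machine$integer.max - 1L, 1L))
        pred[test_idx] <- predict_classifier(classifier_tag, fit, xte, levels(y))
      }
      tp <- sum(pred == pos & y == pos); fn <- sum(pred != pos & y == pos)
      tn <- sum(pred != pos & y != pos); fp <- sum(pred == pos & y != pos)
      c(acc = 100 * mean(pred == y), TP = tp, FP = fp, TN = tn, FN = fn)
    })
  })
  mat <- do.call(rbind, per_repeat)
  confusion <- colMeans(mat[, c("TP", "FP", "TN", "FN"), drop = FALSE])
  stats_ <- confusion_stats(confusion)
  structure(list(
    mean_accuracy = mean(mat[, "acc"]),
    sd_accuracy = stats::sd(mat[, "acc"]),
    accuracies = unname(mat[, "acc"]),
    confusion = confusion,
    sensitivity = 100 * stats_[["sensitivity"]],
    specificity = 100 * stats_[["specificity"]],
    classifier = classifier_tag, folds = folds, repeats = repeats,
    n = n, seed = seed
  ), class = "fcn_cv")
}

#' @export
print.fcn_cv <- function(x, ...) {
  cat(sprintf(
    "<fcn_cv> %s, %d-fold x %d repeats on %d subjects\n  accuracy %.1f%% +/- %.1f%%, sens %.1f%%, spec %.1f%%\n",
    x$classifier, x$folds, x$repeats, x$n,
    x$mean_accuracy, x$sd_accuracy, x$sensitivity, x$specificity
  ))
  invisible(x)
}

default_param_grids <- function() {
  list(
    none = list(list()),
    mds = list(list(p = "auto")),
    isomap = list(list(k = 5L, p = "auto")),
    dmaps = list(list(sigma = NULL, t = 1L, p = "auto")),
    kpca = list(list(gamma = NULL, p = "auto")),
    lle = list(list(k = 7L, p = "auto"))
  )
}

#' Sweep method x metric x parameters x threshold x classifier
#'
#' Full factorial sweep over embedding methods (plus the raw-matrix
#' baseline `"none"`), distance metrics, method parameter grids, the
#' proportional-threshold grid and classifiers; every configuration is
#' scored by [repeated_kfold_cv()]. Per-subject distance matrices are
#' computed once per metric and reused; for diffusion maps a single global
#' `sigma` is selected from the whole cohort's distance matrices (the
#' sum-of-weights rule) unless the grid supplies one. Configurations that
#' fail (e.g. disconnected neighbor graphs for too many subjects) are
#' recorded with their error and skipped, not fatal.
#'
#' @param cohort Cohort tibble (see [assemble_features()]).
#' @param methods Character vector of methods; default all five plus
#'   `"none"`.
#' @param metrics Character vector of metrics; default both.
#' @param param_grids Named list (by method) of lists of parameter lists;
#'   defaults to one default setting per method (see
#'   `default_param_grids()`).
#' @param pt_grid Proportional-threshold grid; default
#'   `seq(0.20, 0.70, by = 0.02)` (26 points).
#' @param classifiers Character vector of classifier tags; default
#'   `"rsvm"`.
#' @param folds,repeats,seed Passed to [repeated_kfold_cv()].
#' @param max_lag Maximum lag for the cross-correlation metric.
#' @return An object of class `"fcn_sweep"`: `results` (one tibble row per
#'   configuration: method, metric, params, pt, classifier, accuracy
#'   mean/SD, sensitivity, specificity, n subjects, `best` flag marking
#'   the best row per method x metric) and `failures` (tibble of skipped
#'   configurations).
#' @export
sweep_configurations <- function(cohort,
                                 methods = c("none", "mds", "isomap", "dmaps", "kpca", "lle"),
                                 metrics = c("cross_correlation", "euclidean"),
                                 param_grids = default_param_grids(),
                                 pt_grid = seq(0.20, 0.70, by = 0.02),
                                 classifiers = "rsvm",
                                 folds = 10L, repeats = 10L, seed = 1L,
                                 max_lag = 3L) {
  results <- list()
  failures <- list()
  for (metric in metrics) {
    Ds <- lapply(cohort$timecourses, distance_for_metric, metric = metric,
                 max_lag = max_lag)
    sigma_global <- if ("dmaps" %in% methods) select_sigma(Ds)$sigma
    for (method in methods) {
      grid <- param_grids[[method]] %||% list(list())
      for (params in grid) {
        if (method == "dmaps" && is.null(params$sigma)) params$sigma <- sigma_global
        label <- param_label(method, params)
        # per-subject embedding; subjects failing this configuration are
        # excluded (up to the 20% budget), mirroring assemble_features()
        config_D <- lapply(Ds, function(D) {
          tryCatch(subject_config_distance(D, method = method, params = params),
                   error = function(e) e)
        })
        ok <- !vapply(config_D, inherits, logical(1), "error")
        if (sum(!ok) > 0.2 * length(config_D)) {
          failures[[length(failures) + 1L]] <- tibble::tibble(
            method = method, metric = metric, params = label,
            error = conditionMessage(config_D[[which(!ok)[1L]]])
          )
          next
        }
        for (pt in pt_grid) {
          ft <- tryCatch({
            feats <- dplyr::bind_rows(lapply(which(ok), function(i) {
              graph_features(config_D[[i]], pt)
            }))
            tibble::tibble(
              subject_id = cohort$subject_id[ok], group = cohort$group[ok],
              L = feats$L, Cg = feats$Cg, Mk = feats$Mk
            )
          }, error = function(e) e)
          if (inherits(ft, "error")) {
            failures[[length(failures) + 1L]] <- tibble::tibble(
              method = method, metric = metric,
              params = label, error = conditionMessage(ft)
            )
            next
          }
          for (clf in classifiers) {
            cv <- repeated_kfold_cv(ft, clf, folds = folds, repeats = repeats,
                                    seed = seed)
            results[[length(results) + 1L]] <- tibble::tibble(
              method = method, metric = metric, params = label,
              pt = pt, classifier = clf,
              accuracy = cv$mean_accuracy, sd = cv$sd_accuracy,
              sensitivity = cv$sensitivity, specificity = cv$specificity,
              n_subjects = cv$n
            )
          }
        }
      }
    }
  }
  results <- dplyr::bind_rows(results)
  if (nrow(results) > 0L) {
    results <- dplyr::ungroup(dplyr::mutate(
      dplyr::group_by(results, .data$method, .data$metric),
      best = seq_along(.data$accuracy) == which.max(.data$accuracy)
    ))
  }
  structure(list(
    results = results,
    failures = dplyr::bind_rows(failures)
  ), class = "fcn_sweep")
}

param_label <- function(method, params) {
  if (length(params) == 0L) return("-")
  paste(vapply(names(params), function(nm) {
    v <- params[[nm]]
    if (is.null(v)) "auto" else paste0(nm, "=", format(v, digits = 3))
  }, character(1)), collapse = ", ")
}

#' @export
print.fcn_sweep <- function(x, ...) {
  cat(sprintf("<fcn_sweep> %d configurations scored, %d failed\n",
              nrow(x$results), nrow(x$failures)))
  best <- dplyr::filter(x$results, .data$best)
  if (nrow(best) > 0L) {
    cat("best per method x metric:\n")
    print(as.data.frame(dplyr::select(
      best, "method", "metric", "pt", "classifier", "accuracy", "sd"
    )), row.names = FALSE, digits = 3)
  }
  invisible(x)
}
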