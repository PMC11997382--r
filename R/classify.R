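#' Enumerate feature combinations
#'
#' All subsets of the seven hemodynamic features with between `min_size` and
#' `max_size` members (one-dimensional features are excluded by default,
#' giving the 120 combinations of 2 to 7 features). Order is deterministic:
#' by size, then lexicographic by feature name.
#'
#' @param n_features How many of the canonical features to draw from.
#' @param min_size,max_size Subset size bounds.
#' @return List of character vectors (feature names). Each combination is
#'   applied to both chromophores, so a combination of k features yields a
#'   2k-dimensional input.
#' @examples
#' length(enumerate_combos())   # 120
#' @export
enumerate_combos <- function(n_features = 7, min_size = 2, max_size = 7) {
  if (!(min_size >= 1 && min_size <= max_size && max_size <= n_features)) {
    stop("invalid combination bounds", call. = FALSE)
  }
  feats <- sort(feature_names()[seq_len(n_features)])
  out <- list()
  for (k in min_size:max_size) {
    sets <- utils::combn(feats, k, simplify = FALSE)
    ord <- order(vapply(sets, paste, character(1), collapse = "\r"))
    out <- c(out, sets[ord])
  }
  out
}

# Feature-matrix columns for a combination (both chromophores).
combo_columns <- function(combo) {
  c(paste0("HbO_", combo), paste0("HbR_", combo))
}

# Extract (X, y, subject) for one ROI from a wide feature table.
feature_matrix <- function(features, roi, combo) {
  rows <- features[features$roi == roi, , drop = FALSE]
  if (nrow(rows) == 0) stop("no features for ROI ", roi, call. = FALSE)
  cols <- combo_columns(combo)
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  list(X = as.matrix(rows[, cols, drop = FALSE]), y = rows$label,
       subject = rows$subject_id)
}

# Partition subjects into k folds, shuffled deterministically by seed.
subject_folds <- function(subjects, k, seed) {
  ids <- unique(subjects)
  if (k > length(ids)) {
    stop("k = ", k, " folds exceed the ", length(ids), " subjects",
         call. = FALSE)
  }
  shuffled <- with_local_seed(seed, sample(ids))
  fold_of <- rep(seq_len(k), length.out = length(ids))
  stats::setNames(fold_of, shuffled)
}

#' Cross-validated accuracy of an SVM on one feature combination
#'
#' Stratified, subject-grouped k-fold cross-validation: both condition
#' samples (imagery and rest) of a subject stay in the same fold, which keeps
#' folds label-balanced and avoids leakage between the dependent samples of
#' one subject. Min-max feature scaling is re-fitted inside every training
#' fold.
#'
#' @param features Wide feature table (see [subject_features()]).
#' @param roi ROI to classify.
#' @param combo Character vector of feature names.
#' @param params [svm_params()].
#' @param k Number of folds.
#' @param seed Seed controlling the fold shuffle.
#' @param folds Optional precomputed fold assignment (named integer vector
#'   subject -> fold), overriding `k`/`seed`.
#' @return Accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(features, roi, combo, params, k = 20, seed = 1,
                        folds = NULL) {
  fm <- feature_matrix(features, roi, combo)
  if (length(unique(fm$y)) < 2) stop("both labels required", call. = FALSE)
  if (is.null(folds)) folds <- subject_folds(fm$subject, k, seed)
  fold_id <- folds[fm$subject]
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    scaling <- minmax_fit(fm$X[tr, , drop = FALSE])
    fit <- svm_fit(minmax_apply(scaling, fm$X[tr, , drop = FALSE]),
                   fm$y[tr], params)
    pred <- svm_predict(fit, minmax_apply(scaling, fm$X[!tr, , drop = FALSE]))
    correct <- correct + sum(pred == fm$y[!tr])
  }
  correct / nrow(fm$X)
}

#' Genetic-algorithm configuration
#'
#' Real-valued GA over (C, gamma) with tournament selection, arithmetic
#' (blend) crossover, Gaussian mutation and single-individual elitism.
#' The full-scale defaults are population 20 and 50 generations; both are
#' freely reducible for desk-scale runs.
#'
#' @param population_size,generations GA size.
#' @param crossover_rate,mutation_rate Probabilities in `[0, 1]`.
#' @param c_range,gamma_range Search bounds (positive).
#' @param cv_folds Cross-validation folds used by the fitness function.
#' @param seed Seed; drives initialisation, GA operators and the fold split.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 20, generations = 50,
                      crossover_rate = 0.7, mutation_rate = 0.05,
                      c_range = c(0.01, 10), gamma_range = c(0.01, 10),
                      cv_folds = 20, seed = 1) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            all(c_range > 0), all(gamma_range > 0))
  structure(
    list(population_size = population_size, generations = generations,
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         c_range = sort(c_range), gamma_range = sort(gamma_range),
         cv_folds = cv_folds, seed = seed),
    class = "ga_config"
  )
}

#' GA search for SVM hyperparameters
#'
#' Maximises the subject-grouped cross-validation accuracy of the RBF SVM
#' over (C, gamma) within the configured bounds. The fold partition is drawn
#' once from the GA seed and held fixed across all fitness evaluations, so
#' the search is deterministic given the seed and individuals are compared
#' on identical folds.
#'
#' @param features Wide feature table.
#' @param roi ROI to classify.
#' @param combo Feature combination (character vector).
#' @param ga A [ga_config()].
#' @return List with `params` ([svm_params()]), `accuracy` (best CV
#'   accuracy) and `evaluations`.
#' @export
ga_optimize <- function(features, roi, combo, ga = ga_config()) {
  if (length(combo) == 0) stop("empty feature combination", call. = FALSE)
  fm <- feature_matrix(features, roi, combo)
  folds <- subject_folds(fm$subject, ga$cv_folds, ga$seed)
  fitness <- function(ind) {
    cv_accuracy(features, roi, combo, svm_params(ind[1], ind[2]),
                folds = folds)
  }
  lo <- c(ga$c_range[1], ga$gamma_range[1])
  hi <- c(ga$c_range[2], ga$gamma_range[2])
  n_eval <- 0L
  with_local_seed(ga$seed, {
    pop <- cbind(stats::runif(ga$population_size, lo[1], hi[1]),
                 stats::runif(ga$population_size, lo[2], hi[2]))
    fit <- apply(pop, 1, fitness)
    n_eval <- n_eval + nrow(pop)
    for (g in seq_len(ga$generations)) {
      elite_idx <- which.max(fit)
      new_pop <- matrix(0, ga$population_size, 2)
      new_pop[1, ] <- pop[elite_idx, ]
      for (i in 2:ga$population_size) {
        tournament <- function() {
          cand <- sample.int(ga$population_size, 3, replace = TRUE)
          pop[cand[which.max(fit[cand])], ]
        }
        p1 <- tournament()
        child <- p1
        if (stats::runif(1) < ga$crossover_rate) {
          p2 <- tournament()
          u <- stats::runif(2)
          child <- u * p1 + (1 - u) * p2
        }
        mut <- stats::runif(2) < ga$mutation_rate
        if (any(mut)) {
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, 0.1 * (hi - lo)[mut])
        }
        new_pop[i, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- new_pop
      fit <- apply(pop, 1, fitness)
      n_eval <- n_eval + nrow(pop)
    }
    best <- which.max(fit)
    list(params = svm_params(pop[best, 1], pop[best, 2]),
         accuracy = fit[best], evaluations = n_eval)
  })
}

#' Train per-ROI classifiers with combination search
#'
#' For each ROI, runs [ga_optimize()] on every candidate feature combination
#' and keeps the combination/parameters with the highest cross-validation
#' accuracy (ties broken by fewer features, then lexicographically). The
#' winning model is refitted on the full training set with min-max scaling
#' fitted on that set.
#'
#' @param features Wide training feature table (healthy controls).
#' @param combos List of feature combinations (default: all 120).
#' @param rois ROIs to model (default: the four motor ROIs).
#' @param ga A [ga_config()].
#' @return Named list (per ROI) of `trained_classifier` objects: `roi`,
#'   `combo`, `params`, `cv_accuracy`, `scaling`, `fit`. ROIs without
#'   features are skipped with a warning.
#' @export
select_model <- function(features, combos = enumerate_combos(),
                         rois = motor_rois(), ga = ga_config()) {
  out <- list()
  for (roi in rois) {
    if (!any(features$roi == roi)) {
      warning("no training features for ROI ", roi, "; skipped",
              call. = FALSE)
      next
    }
    best <- NULL
    for (combo in combos) {
      res <- ga_optimize(features, roi, combo, ga)
      better <- is.null(best) ||
        res$accuracy > best$accuracy + 1e-12 ||
        (abs(res$accuracy - best$accuracy) <= 1e-12 &&
           (length(combo) < length(best$combo) ||
              (length(combo) == length(best$combo) &&
                 paste(combo, collapse = ",") <
                   paste(best$combo, collapse = ","))))
      if (better) best <- list(combo = combo, params = res$params,
                               accuracy = res$accuracy)
    }
    fm <- feature_matrix(features, roi, best$combo)
    scaling <- minmax_fit(fm$X)
    fit <- svm_fit(minmax_apply(scaling, fm$X), fm$y, best$params)
    out[[roi]] <- structure(
      list(roi = roi, combo = best$combo, params = best$params,
           cv_accuracy = best$accuracy, scaling = scaling, fit = fit),
      class = "trained_classifier"
    )
  }
  out
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf(
    "RBF-SVM for %s: features {%s}, C = %.3g, gamma = %.3g, CV accuracy %.1f%%\n",
    x$roi, paste(x$combo, collapse = ", "), x$params$C, x$params$gamma,
    100 * x$cv_accuracy
  ))
  invisible(x)
}

#' Command-following decision rule from the two predicted labels
#'
#' Under the strict rule a subject shows an fNIRS response iff the imagery
#' sample is labeled 1 and the rest sample 0; the lenient rule requires only
#' the imagery label.
#'
#' @param imagery_label,rest_label Predicted labels in `{0, 1}`.
#' @param rule `"strict"` or `"lenient"`.
#' @return Logical.
#' @export
decide_response <- function(imagery_label, rest_label,
                            rule = c("strict", "lenient")) {
  rule <- match.arg(rule)
  stopifnot(imagery_label %in% c(0L, 1L), rest_label %in% c(0L, 1L))
  if (rule == "strict") imagery_label == 1L && rest_label == 0L
  else imagery_label == 1L
}

#' Predict one subject's response with a trained classifier
#'
#' Applies the training-set scaling, predicts labels for the subject's
#' imagery and rest feature vectors and derives the response decision.
#'
#' @param model A `trained_classifier`.
#' @param imagery_features,rest_features Named numeric vectors (or one-row
#'   data frames) containing at least the model's feature columns.
#' @param rule Decision rule, see [decide_response()].
#' @return List `subject_prediction`: `roi`, `imagery_label`, `rest_label`,
#'   `response`.
#' @export
predict_subject <- function(model, imagery_features, rest_features,
                            rule = c("strict", "lenient")) {
  rule <- match.arg(rule)
  cols <- combo_columns(model$combo)
  grab <- function(v) {
    if (is.data.frame(v)) v <- as.list(v[1, , drop = FALSE])
    if (!all(cols %in% names(v))) {
      stop("missing feature(s): ",
           paste(setdiff(cols, names(v)), collapse = ", "), call. = FALSE)
    }
    matrix(as.numeric(unlist(v[cols])), nrow = 1,
           dimnames = list(NULL, cols))
  }
  X <- rbind(grab(imagery_features), grab(rest_features))
  pred <- svm_predict(model$fit, minmax_apply(model$scaling, X))
  structure(
    list(roi = model$roi, imagery_label = pred[1], rest_label = pred[2],
         response = decide_response(pred[1], pred[2], rule)),
    class = "subject_prediction"
  )
}

#' Predict responses for every subject in a feature table
#'
#' @param models Named list of trained classifiers from [select_model()].
#' @param features Wide feature table of the test subjects.
#' @param rois ROIs to predict (default: those with a model).
#' @param rule Decision rule.
#' @return Data frame: `subject_id`, `roi`, `imagery_label`, `rest_label`,
#'   `response`. Subjects missing an ROI are skipped for that ROI.
#' @export
predict_cohort <- function(models, features, rois = names(models),
                           rule = c("strict", "lenient")) {
  rule <- match.arg(rule)
  rows <- list()
  for (roi in rois) {
    model <- models[[roi]]
    sub <- features[features$roi == roi, , drop = FALSE]
    for (id in unique(sub$subject_id)) {
      im <- sub[sub$subject_id == id & sub$condition == "imagery", ]
      re <- sub[sub$subject_id == id & sub$condition == "rest", ]
      if (nrow(im) != 1 || nrow(re) != 1) next
      p <- predict_subject(model, im[1, ], re[1, ], rule)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, roi = roi, imagery_label = p$imagery_label,
        rest_label = p$rest_label, response = p$response,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
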