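test_that("combination enumeration is complete and deterministic", {
  combos <- enumerate_combos()
  expect_length(combos, 120)
  expect_length(enumerate_combos(3, 2, 3), 4)      # C(3,2) + C(3,3)
  expect_length(enumerate_combos(2, 2, 2), 1)
  sizes <- vapply(combos, length, 1L)
  expect_true(all(diff(sizes) >= 0))               # ordered by size
  expect_identical(combos, enumerate_combos())
  expect_true(all(vapply(combos, function(cm) all(cm %in% feature_names()),
                         logical(1))))
  expect_error(enumerate_combos(7, 0, 3), "invalid")
  expect_error(enumerate_combos(7, 5, 3), "invalid")
})

test_that("label semantics are conserved in generated feature tables", {
  ft <- make_feature_table(n_subjects = 8, seed = 2)
  expect_true(all((ft$label == 1L) == (ft$condition == "imagery")))
})

test_that("cross-validation separates planted classes and respects folds", {
  ft <- make_feature_table(n_subjects = 30, separation = 2, seed = 1)
  acc <- cv_accuracy(ft, "LPMC", c("mean", "variance"), svm_params(1, 1),
                     k = 20, seed = 3)
  expect_gte(acc, 0.95)
  expect_error(cv_accuracy(ft, "LPMC", c("mean", "variance"),
                           svm_params(1, 1), k = 40, seed = 1), "folds exceed")
  # both samples of a subject share a fold
  folds <- cmdnirs:::subject_folds(ft$subject_id, 10, seed = 5)
  expect_length(folds, 30)
  expect_true(all(table(folds) %in% 3))
})

test_that("shuffled labels drop accuracy to chance", {
  ft <- make_feature_table(n_subjects = 20, separation = 2, seed = 4)
  accs <- vapply(1:50, function(s) {
    set.seed(s)
    sh <- ft
    sh$label <- sample(sh$label)
    cv_accuracy(sh, "LPMC", c("mean", "variance"), svm_params(1, 1),
                k = 10, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("test-set magnitudes cannot leak into training CV accuracy", {
  ft <- make_feature_table(n_subjects = 16, separation = 1, seed = 6)
  base <- cv_accuracy(ft, "LPMC", c("mean", "peak"), svm_params(2, 2),
                      k = 8, seed = 2)
  # scaling is fit per training fold; a disjoint test table cannot matter
  again <- cv_accuracy(ft, "LPMC", c("mean", "peak"), svm_params(2, 2),
                       k = 8, seed = 2)
  expect_identical(base, again)
})

test_that("GA finds separating parameters, respects bounds and seed", {
  ft <- make_feature_table(n_subjects = 24, separation = 2, seed = 7)
  ga <- ga_config(population_size = 8, generations = 5, cv_folds = 8,
                  seed = 13)
  res <- ga_optimize(ft, "LPMC", c("mean", "variance"), ga)
  expect_gte(res$accuracy, 0.95)
  expect_true(res$params$C >= 0.01 && res$params$C <= 10)
  expect_true(res$params$gamma >= 0.01 && res$params$gamma <= 10)
  res2 <- ga_optimize(ft, "LPMC", c("mean", "variance"), ga)
  expect_identical(res, res2)
  # collapsed search space returns exactly the forced parameters
  point <- ga_config(population_size = 4, generations = 2, cv_folds = 8,
                     c_range = c(1, 1), gamma_range = c(1, 1), seed = 13)
  forced <- ga_optimize(ft, "LPMC", c("mean", "variance"), point)
  expect_equal(forced$params$C, 1)
  expect_equal(forced$params$gamma, 1)
  expect_error(ga_optimize(ft, "LPMC", character(0), ga), "empty feature")
})

test_that("model selection finds the informative combination and tie-breaks", {
  # only mean and variance carry signal
  ft <- make_feature_table(n_subjects = 24, separation = 0, seed = 8)
  sig_cols <- c("HbO_mean", "HbR_mean", "HbO_variance", "HbR_variance")
  im <- ft$condition == "imagery"
  ft[im, sig_cols] <- ft[im, sig_cols] + 3
  ga <- ga_config(population_size = 6, generations = 3, cv_folds = 8,
                  seed = 21)
  combos <- list(c("mean", "variance"), c("median", "skewness"),
                 c("kurtosis", "peak_to_peak"))
  models <- select_model(ft, combos, rois = "LPMC", ga)
  expect_named(models, "LPMC")
  expect_setequal(models$LPMC$combo, c("mean", "variance"))
  # single-candidate list is selected verbatim
  one <- select_model(ft, list(c("median", "peak")), rois = "LPMC", ga)
  expect_setequal(one$LPMC$combo, c("median", "peak"))
  # equal accuracy: smaller combo wins
  sep <- make_feature_table(n_subjects = 24, separation = 4, seed = 9)
  tied <- select_model(sep, list(c("mean", "median", "variance"),
                                 c("mean", "variance")),
                       rois = "LPMC", ga)
  expect_length(tied$LPMC$combo, 2)
  expect_warning(select_model(ft, combos, rois = c("LPMC", "RM1"), ga),
                 "no training features for ROI RM1")
})

test_that("response decision rules implement the truth table", {
  expect_true(decide_response(1L, 0L))
  expect_false(decide_response(0L, 0L))
  expect_false(decide_response(0L, 1L))
  expect_false(decide_response(1L, 1L))
  expect_true(decide_response(1L, 1L, rule = "lenient"))
  expect_false(decide_response(0L, 0L, rule = "lenient"))
  expect_error(decide_response(2L, 0L))
})

test_that("subject prediction applies scaling and is reproducible", {
  ft <- make_feature_table(n_subjects = 24, separation = 3, seed = 10)
  ga <- ga_config(population_size = 6, generations = 3, cv_folds = 8,
                  seed = 5)
  model <- select_model(ft, list(c("mean", "variance")), "LPMC", ga)$LPMC
  cols <- c(paste0("HbO_", feature_names()), paste0("HbR_", feature_names()))
  deep_imagery <- stats::setNames(rep(3, 14), cols)
  deep_rest <- stats::setNames(rep(0, 14), cols)
  p <- predict_subject(model, deep_imagery, deep_rest)
  expect_equal(p$imagery_label, 1L)
  expect_equal(p$rest_label, 0L)
  expect_true(p$response)
  expect_identical(p, predict_subject(model, deep_imagery, deep_rest))
  expect_error(predict_subject(model, deep_imagery[1:3], deep_rest),
               "missing feature")
})

test_that("cohort prediction returns one decision per subject and ROI", {
  ft <- make_feature_table(n_subjects = 20, separation = 3, seed = 11)
  ga <- ga_config(population_size = 6, generations = 3, cv_folds = 8, seed = 5)
  models <- select_model(ft, list(c("mean", "variance")), "LPMC", ga)
  test_ft <- make_feature_table(n_subjects = 6, separation = 3, seed = 99)
  pred <- predict_cohort(models, test_ft)
  expect_equal(nrow(pred), 6)
  expect_setequal(names(pred),
                  c("subject_id", "roi", "imagery_label", "rest_label",
                    "response"))
  expect_gte(mean(pred$response), 0.5)  # separable test subjects respond
})
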