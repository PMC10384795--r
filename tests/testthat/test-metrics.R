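test_that("accuracy and F1 reproduce hand-computed values exactly", {
  m <- compute_metrics(50, 0, 50, 0)
  expect_identical(m$accuracy, 1)
  expect_identical(m$F1, 1)
  m2 <- compute_metrics(95, 5, 93, 7)
  expect_equal(m2$accuracy, 0.94, tolerance = 1e-15)
  expect_equal(m2$F1, 190 / 202, tolerance = 1e-15)
  m3 <- compute_metrics(0, 0, 10, 5)   # no true/predicted positives
  expect_identical(m3$F1, 0)
  expect_warning(m4 <- compute_metrics(0, 0, 10, 0), "F1")
  expect_identical(m4$F1, 0)
  expect_error(compute_metrics(0, 0, 0, 0), "zero")
  expect_error(compute_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("classification reports count the confusion cells conservatively", {
  truth <- factor(rep(c("filled", "unfilled"), each = 10))
  pred <- truth
  pred[c(3, 15)] <- rev(levels(truth))[match(pred[c(3, 15)], levels(truth))]
  rep <- classification_report(truth, pred, times = rep(0.01, 20))
  expect_equal(rep$TP + rep$FP + rep$TN + rep$FN, 20)
  expect_equal(rep$FN, 1)
  expect_equal(rep$FP, 1)
  expect_equal(rep$accuracy, 18 / 20)
  expect_equal(rep$efficiency, 0.2)
})

test_that("stratified folds partition each class evenly", {
  set.seed(30)
  labels <- factor(rep(c("a", "b"), c(40, 60)))
  folds <- graincloud:::stratified_folds(labels, 5)
  expect_length(folds, 100)
  expect_true(all(folds %in% 1:5))
  expect_true(all(table(folds, labels)[, "a"] == 8))
  expect_true(all(table(folds, labels)[, "b"] == 12))
})

make_trait_table <- function(n_per_class, v_gap = 1.25, seed = 1) {
  # synthetic 11-trait table, separable by construction: the volume gap
  # between classes (v_gap) dominates the within-class shape variation
  set.seed(seed)
  n <- 2 * n_per_class
  cls <- factor(rep(c("filled", "unfilled"), each = n_per_class))
  L <- rnorm(n, 7, 0.1)
  W <- rnorm(n, 3, 0.07)
  H <- rnorm(n, 2, 0.05)
  base_v <- pi / 6 * L * W * H
  V <- base_v * ifelse(cls == "filled", 1, 1 / v_gap) * rnorm(n, 1, 0.03)
  S0 <- 45 + 2 * (L - 7) + rnorm(n, 0, 1)
  tab <- data.frame(L = L, W = W, H = H, V = V, S0 = S0,
                    PA_x = W * H * 0.8 + rnorm(n, 0, 0.2),
                    PA_y = L * H * 0.8 + rnorm(n, 0, 0.3),
                    PA_z = L * W * 0.8 + rnorm(n, 0, 0.4),
                    PP_x = 2 * (W + H) + rnorm(n, 0, 0.2),
                    PP_y = 2 * (L + H) + rnorm(n, 0, 0.3),
                    PP_z = 2 * (L + W) + rnorm(n, 0, 0.3))
  list(traits = tab, labels = cls)
}

test_that("all six models separate a volume-shifted trait table", {
  tt <- make_trait_table(40, v_gap = 1.25, seed = 3)
  cv <- crossval_classifiers(tt$traits, tt$labels, k = 5, seed = 11)
  expect_setequal(names(cv), c("dt", "rf", "svm", "nb", "bpnn", "xgb"))
  for (m in names(cv)) {
    expect_gte(cv[[m]]$mean_accuracy, 0.90)
    expect_length(cv[[m]]$fold_accuracy, 5)
  }
})

test_that("permuted labels drive every model to chance level", {
  tt <- make_trait_table(150, v_gap = 1.25, seed = 4)
  set.seed(99)
  shuffled <- sample(tt$labels)
  cv <- crossval_classifiers(tt$traits, shuffled, k = 5, seed = 12)
  for (m in names(cv)) {
    expect_gte(cv[[m]]$mean_accuracy, 0.4)
    expect_lte(cv[[m]]$mean_accuracy, 0.6)
  }
})

test_that("cross-validation rejects bad inputs and unknown models", {
  tt <- make_trait_table(10)
  expect_error(crossval_classifiers(tt$traits, tt$labels,
                                    models = "boost9000"), "unknown model")
  bad <- tt$traits
  bad$V[1] <- NA
  expect_error(crossval_classifiers(bad, tt$labels), "V")
  expect_error(crossval_classifiers(tt$traits, tt$labels, k = 1), "at least 2")
})

test_that("grid search only selects values inside the declared grid", {
  tt <- make_trait_table(25, seed = 6)
  cv <- crossval_classifiers(tt$traits, tt$labels, models = c("dt", "svm"),
                             k = 3, seed = 13)
  grids <- graincloud:::default_grids()
  for (m in c("dt", "svm")) {
    for (ch in cv[[m]]$chosen) {
      hit <- any(apply(grids[[m]], 1, function(row)
        all(abs(as.numeric(row) - as.numeric(ch)) < 1e-12)))
      expect_true(hit)
    }
  }
})
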