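test_that("fold assignment is balanced, stratified and reproducible", {
  f <- make_folds(10, 5, seed = 1)
  expect_equal(sort(tabulate(f$fold_of, 5)), rep(2L, 5))
  f3 <- make_folds(10, 3, seed = 1)
  expect_equal(sort(tabulate(f3$fold_of, 3)), c(3L, 3L, 4L))
  expect_equal(make_folds(10, 3, seed = 1)$fold_of, f3$fold_of)
  expect_false(identical(make_folds(10, 3, seed = 2)$fold_of, f3$fold_of))
  expect_error(make_folds(5, 6), "J")

  y <- rep(c(0L, 1L), c(30, 20))
  fs <- make_folds(50, 5, seed = 3, stratify_labels = y)
  per_fold_pos <- tapply(y, fs$fold_of, sum)
  expect_lte(diff(range(per_fold_pos)), 1)
  expect_error(make_folds(50, 25, seed = 1,
                          stratify_labels = rep(c(0L, 1L), c(45, 5))),
               "fewer than")
})

test_that("out-of-fold predictions come from models that never saw the fold", {
  # hand-evaluated example: a majority-class learner with opposite-label
  # halves must predict each half as the *other* half's class
  m <- descriptor_matrix(matrix(rnorm(8), 4, 2,
                                dimnames = list(paste0("m", 1:4),
                                                c("a", "b"))),
                         labels = c(1, 1, 0, 0))
  l1 <- fit_base_oof(m, list(learner_majority()),
                     manual_folds(c(1, 1, 2, 2)))
  expect_equal(unname(l1$z[, 1]), c(0, 0, 1, 1))

  # a constant learner is unaffected by folds
  l2 <- fit_base_oof(m, list(learner_constant(0.5)),
                     manual_folds(c(1, 2, 1, 2)))
  expect_equal(unname(l2$z[, 1]), rep(0.5, 4))
})

test_that("a memorizing learner gains nothing on shuffled labels (no leakage)", {
  aucs <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(paste0("m", 1:200), paste0("f", 1:5)))
    y <- sample(rep(c(0L, 1L), 100))           # labels carry no signal
    m <- descriptor_matrix(x, labels = y)
    l1 <- fit_base_oof(m, list(learner_knn1()),
                       make_folds(200, 5, seed = s, stratify_labels = y))
    aucs[s] <- auc_mw(y, l1$z[, 1])
  }
  expect_true(all(aucs > 0.35 & aucs < 0.65))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # the same memorizer predicting its own training rows scores ~1:
  # this is the leak the out-of-fold protocol prevents
  set.seed(1)
  x <- matrix(rnorm(200 * 5), 200, 5)
  y <- sample(rep(c(0L, 1L), 100))
  knn <- learner_knn1()
  leaked <- knn$predict(knn$fit(x, y), x)
  expect_gt(auc_mw(y, leaked), 0.95)
})

test_that("the super learner is normalized and fits separable level-one data", {
  set.seed(8)
  z <- matrix(runif(400), 200, 2, dimnames = list(NULL, c("rf", "xgb")))
  y <- as.integer(z[, 1] > 0.5)               # separable in one learner
  l1 <- structure(list(z = z, y = y, learner_names = c("rf", "xgb"),
                       folds = manual_folds(rep(1:2, 100))),
                  class = "level_one_data")
  sup <- fit_super_learner(l1, hidden = c(16, 8), epochs = 50, seed = 2)
  p <- predict(sup, z)
  expect_equal(rowSums(p), rep(1, 200), tolerance = 1e-6)
  expect_gte(mean((p[, "1"] >= 0.5) == (y == 1)), 0.95)
  # shuffled labels give chance-level internal AUC
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    ysh <- sample(y)
    sup0 <- fit_super_learner(
      structure(list(z = z, y = ysh, learner_names = c("rf", "xgb"),
                     folds = manual_folds(rep(1:2, 100))),
                class = "level_one_data"),
      hidden = c(16, 8), epochs = 30, seed = s)
    auc_mw(ysh, predict(sup0, z)[, "1"])
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("stacked model predicts consistently and validates features", {
  d <- gen_descriptor_matrix(n = 120, p = 12, n_informative = 4,
                             class_sep = 2, n_sparse = 0, n_constant = 0,
                             n_duplicated = 0, seed = 21)
  fit <- cs_stack(d$matrix, folds = 5, hidden = c(8, 4), epochs = 30,
                  seed = 21)
  x <- d$matrix$values
  p1 <- predict(fit, x)
  expect_true(all(p1$proba >= 0 & p1$proba <= 1))
  expect_equal(p1$label, as.integer(p1$proba >= 0.5))
  # permuting feature columns by name changes nothing
  p2 <- predict(fit, x[, rev(colnames(x))])
  expect_equal(p2$proba, p1$proba)
  expect_error(predict(fit, x[, -1]), "missing")
  # deterministic refit
  fit2 <- cs_stack(d$matrix, folds = 5, hidden = c(8, 4), epochs = 30,
                   seed = 21)
  expect_equal(predict(fit2, x)$proba, p1$proba)
  # a high separation problem is essentially solved out of fold
  expect_gt(fit$oof_metrics$rf$auc, 0.9)
  expect_gte(fit$entropy, 0)
  expect_lte(fit$entropy, 1)
})

test_that("rank-based AUC cross-checks against pROC on stacked output", {
  skip_if_not_installed("pROC")
  d <- gen_descriptor_matrix(n = 80, p = 10, class_sep = 1, n_sparse = 0,
                             n_constant = 0, n_duplicated = 0, seed = 5)
  fit <- cs_stack(d$matrix, folds = 4, hidden = c(4), epochs = 20, seed = 5)
  p <- predict(fit, d$matrix$values)$proba
  ours <- auc_mw(d$matrix$labels, p)
  ref <- as.numeric(pROC::auc(pROC::roc(d$matrix$labels, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})
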