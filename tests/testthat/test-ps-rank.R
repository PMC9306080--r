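test_that("beta is the probability-count sum with validated inputs", {
  expect_equal(score_beta(0.75, 11), 11.75)
  expect_equal(score_beta(0, 0), 0)
  expect_equal(score_beta(1, 9), 10)
  expect_error(score_beta(1.2, 1), "f_alpha")
  expect_error(score_beta(0.5, -1), "d_i")
  # monotone in both arguments; d_i dominates across integer counts
  expect_gt(score_beta(0.51, 5), score_beta(0.5, 5))
  expect_gt(score_beta(0.01, 6), score_beta(0.99, 5))
})

test_that("rank_hits reproduces the worked candidate set", {
  preds <- data.frame(id = c("A", "B", "C"),
                      f_alpha = c(0.9, 0.8, 0.7),
                      stringsAsFactors = FALSE)
  profs <- c(A = 10L, B = 13L, C = 9L)
  rk <- rank_hits(preds, profs, threshold_window(9, 12))
  ranked <- rk[!is.na(rk$rank), ]
  expect_equal(ranked$id, c("A", "C"))
  expect_equal(ranked$beta, c(10.9, 9.7))
  expect_equal(ranked$rank, c(1L, 2L))
  expect_false(rk$passed_window[rk$id == "B"])
  expect_true(is.na(rk$rank[rk$id == "B"]))
})

test_that("window, tie and mode rules are honoured", {
  preds <- data.frame(id = c("b", "a"), f_alpha = c(0.5, 0.5),
                      stringsAsFactors = FALSE)
  profs <- c(a = 10L, b = 10L)
  rk <- rank_hits(preds, profs, threshold_window(9, 12))
  expect_equal(rk$id[rk$rank == 1], "a")     # equal beta -> id order

  # all candidates outside the window: empty ranked block, all flagged
  rk2 <- rank_hits(preds, c(a = 2L, b = 20L), threshold_window(9, 12))
  expect_true(all(is.na(rk2$rank)))
  expect_true(all(!rk2$passed_window))

  # sub-threshold predictions are not candidates at all
  preds3 <- data.frame(id = c("a", "b"), f_alpha = c(0.9, 0.2))
  rk3 <- rank_hits(preds3, profs, threshold_window(9, 12))
  expect_equal(rk3$id, "a")

  # evaluation mode keeps only true positives
  rk4 <- rank_hits(preds3, profs, threshold_window(9, 12),
                   truth = c(a = 0L, b = 1L))
  expect_equal(nrow(rk4), 0L)

  # a candidate without a profile is an error naming it
  expect_error(rank_hits(preds3, c(b = 1L), threshold_window(9, 12)), "a")
  expect_error(threshold_window(5, 2), "d_min")
})

test_that("an unbounded window reduces to a plain beta sort", {
  set.seed(31)
  preds <- data.frame(id = sprintf("m%02d", 1:25),
                      f_alpha = runif(25, 0.5, 1))
  profs <- stats::setNames(sample(0:15, 25, replace = TRUE), preds$id)
  rk <- rank_hits(preds, profs, threshold_window(0, 10000L))
  beta <- preds$f_alpha + profs[preds$id]
  oracle <- preds$id[order(-beta, -preds$f_alpha, preds$id)]
  expect_equal(rk$id, oracle)
  # output is a permutation of the candidates
  expect_setequal(rk$id, preds$id)
  expect_equal(sort(rk$rank), 1:25)
})

test_that("the fingerprint network recovers class signal and honours the grid", {
  g <- gen_fingerprint_dataset(n = 120, k_informative = 8, effect = 2,
                               width = 400, seed = 17)
  fit <- ps_net(g$x, g$y, hidden = c(32, 16, 32), epochs = 30,
                grid = list(momentum = 0.9), seed = 17)
  expect_gte(fit$cv_auc, 0.9)
  p <- predict(fit, g$x)
  expect_true(all(p$f_alpha >= 0 & p$f_alpha <= 1))
  expect_equal(p$label, as.integer(p$f_alpha >= 0.5))
  # grid of size 1 selects that point trivially
  expect_equal(fit$best$momentum, 0.9)
  # probabilities from the underlying network are normalized
  pm <- predict(fit$model, g$x)
  expect_equal(unname(rowSums(pm)), rep(1, nrow(g$x)), tolerance = 1e-6)
  # a larger grid records one row per point and picks the best mean AUC
  fit2 <- ps_net(g$x[1:60, ], g$y[1:60], hidden = c(8), epochs = 10,
                 folds = 3, grid = list(momentum = c(0.5, 0.9),
                                        input_dropout = c(0, 0.2)),
                 seed = 3)
  expect_equal(nrow(fit2$cv), 4L)
  expect_equal(fit2$cv_auc, max(fit2$cv$mean_auc))
  # invalid inputs
  expect_error(ps_net(g$x, rep(1L, nrow(g$x))), "single class")
  xa <- g$x; xa[1, 1] <- -1
  expect_error(ps_net(xa, g$y), "non-negative")
})

test_that("a null fingerprint dataset yields chance-level CV AUC", {
  aucs <- vapply(1:10, function(s) {
    g <- gen_fingerprint_dataset(n = 100, k_informative = 5, effect = 0,
                                 width = 150, seed = s)
    fit <- ps_net(g$x, g$y, hidden = c(8), epochs = 15, folds = 5,
                  grid = list(momentum = 0.9), seed = s)
    fit$cv_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})
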