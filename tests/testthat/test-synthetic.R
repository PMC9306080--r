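test_that("descriptor generation is seed-deterministic with a valid manifest", {
  d1 <- gen_descriptor_matrix(n = 60, p = 15, seed = 9)
  d2 <- gen_descriptor_matrix(n = 60, p = 15, seed = 9)
  expect_identical(d1$matrix$values, d2$matrix$values)
  expect_identical(d1$matrix$labels, d2$matrix$labels)
  d3 <- gen_descriptor_matrix(n = 60, p = 15, seed = 10)
  expect_false(identical(d1$matrix$values, d3$matrix$values))
  # classes balanced, planted columns have the promised pathologies
  expect_equal(sum(d1$matrix$labels), 30L)
  v <- d1$matrix$values
  for (nm in d1$manifest$sparse) expect_gt(mean(v[, nm] == 0), 0.85)
  for (nm in d1$manifest$constant) expect_equal(sd(v[, nm]), 0)
  for (nm in d1$manifest$duplicated) {
    src <- sub(".*_of_", "", nm)
    expect_equal(v[, nm], v[, src], ignore_attr = TRUE)
  }
  expect_error(gen_descriptor_matrix(n = 10, p = 4, n_informative = 3,
                                     n_sparse = 3, n_constant = 2,
                                     n_duplicated = 2),
               "exceed")
})

test_that("null descriptor data gives chance-level out-of-fold AUC", {
  aucs <- vapply(1:10, function(s) {
    d <- gen_descriptor_matrix(n = 80, p = 10, n_informative = 4,
                               class_sep = 0, n_sparse = 0, n_constant = 0,
                               n_duplicated = 0, seed = s)
    l1 <- fit_base_oof(d$matrix, list(learner_rf(ntree = 100)),
                       make_folds(80, 4, seed = s,
                                  stratify_labels = d$matrix$labels),
                       seed = s)
    auc_mw(d$matrix$labels, l1$z[, 1])
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("fingerprint generation has the library width and seeded nulls", {
  g <- gen_fingerprint_dataset(n = 20, k_informative = 3, effect = 1, seed = 2)
  expect_equal(ncol(g$x), 4860L)
  expect_true(all(g$x >= 0) && all(g$x == floor(g$x)))
  expect_length(g$manifest$informative, 3L)
  g2 <- gen_fingerprint_dataset(n = 20, k_informative = 3, effect = 1, seed = 2)
  expect_identical(g$x, g2$x)
  expect_error(gen_fingerprint_dataset(n = 10), "n >= 20")
  expect_error(gen_fingerprint_dataset(n = 30, k_informative = 0), "k_informative")
})

test_that("complex generation is deterministic and self-consistent", {
  g1 <- gen_complex(c(hbond = 1, salt_bridge = 1), seed = 3)
  g2 <- gen_complex(c(hbond = 1, salt_bridge = 1), seed = 3)
  expect_identical(g1$pdb, g2$pdb)
  expect_equal(g1$d_i, 2L)
  expect_setequal(g1$expected$type, c("hbond", "salt_bridge"))
  expect_error(gen_complex(c(banana = 1)), "unknown interaction")
  # file writing round-trip
  tf <- tempfile(fileext = ".pdb")
  g3 <- gen_complex(c(hydrophobic = 2), path = tf, seed = 1)
  expect_true(file.exists(tf))
  expect_equal(interaction_profile(parse_complex(tf))$d_i, 2L)
})

test_that("the activity table meets its composition by construction", {
  tab <- gen_activity_table(n_active = 12, n_inactive = 20, seed = 5)
  expect_equal(nrow(tab), 32L)
  expect_equal(sum(tab$ic50_um < 0.05), 12L)
  expect_false(anyDuplicated(tab$id) > 0)
  tab2 <- gen_activity_table(n_active = 12, n_inactive = 20, seed = 5)
  expect_identical(tab, tab2)
  # every SMILES in the pool parses
  ok <- vapply(unique(tab$smiles), function(s) {
    nzchar(trimws(ChemmineOB::convertFormat("SMILES", "CAN", source = s)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("the screening study pairs spaces consistently", {
  st <- gen_screening_study(n_train = 40, n_eval = 20, fp_width = 200,
                            window = threshold_window(9, 12), seed = 8)
  expect_equal(nrow(st$train$descriptors$values), 40L)
  expect_equal(nrow(st$eval$fp), 20L)
  expect_equal(names(st$eval$d_i), rownames(st$eval$fp))
  # actives inside the window, inactives outside
  for (p in list(st$train, st$eval)) {
    expect_true(all(p$d_i[p$y == 1] >= 9 & p$d_i[p$y == 1] <= 12))
    expect_true(all(p$d_i[p$y == 0] < 9 | p$d_i[p$y == 0] > 12))
  }
})
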