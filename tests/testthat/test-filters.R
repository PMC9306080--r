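dm <- function(...) {
  cols <- list(...)
  descriptor_matrix(do.call(cbind, stats::setNames(cols, names(cols))))
}

test_that("sparse filter removes on strict 'more than' zero fraction", {
  m <- dm(a = c(rep(0, 9), 1), b = c(rep(0, 8), 1, 2), c = rnorm(10))
  out <- filter_sparse(m)                       # a: 0.9 > 0.85; b: 0.8 kept
  expect_equal(out$report$removed, "a")
  expect_equal(colnames(out$matrix$values), c("b", "c"))

  m2 <- dm(x = c(rep(0, 17), 1, 2, 3), y = rnorm(20))  # exactly 0.85 kept
  expect_length(filter_sparse(m2)$report$removed, 0)
})

test_that("low-SD filter is strict and supports a relative mode", {
  m <- dm(const = rep(3, 10), alt = rep(c(0, 1), 5), ok = rnorm(10, sd = 2))
  out <- filter_low_sd(m)
  expect_equal(out$report$removed, "const")
  # boundary: SD exactly at the threshold is kept
  v <- rep(c(0, 0.06), 5)                       # sample SD ~ 0.0316 > 0.03
  expect_length(filter_low_sd(dm(v = v), min_sd = stats::sd(v))$report$removed, 0)
  # relative mode compares SD / |mean|
  big <- rnorm(20, mean = 1000, sd = 1)          # CV ~ 0.001 < 0.03
  expect_equal(filter_low_sd(dm(big = big), relative = TRUE)$report$removed,
               "big")
})

test_that("correlation filter keeps the earlier column, greedy left-to-right", {
  set.seed(5)
  x1 <- rnorm(50)
  m <- dm(X1 = x1, X2 = 2 * x1, Z = rnorm(50))
  out <- filter_correlated(m)
  expect_equal(out$report$removed, "X2")

  # anti-correlated duplicates are removed too (absolute rho)
  m2 <- dm(X1 = x1, X2 = -x1)
  expect_equal(filter_correlated(m2)$report$removed, "X2")

  # boundary: rho exactly at the threshold keeps both
  a <- c(1, 2, 3, 4); b <- c(1.1, 2.2, 2.8, 4.3)
  rho <- abs(cor(a, b))
  expect_length(filter_correlated(dm(a = a, b = b),
                                  max_abs_rho = rho)$report$removed, 0)

  # zero-variance columns must be filtered out beforehand
  expect_error(filter_correlated(dm(c = rep(1, 10), z = rnorm(10))),
               "filter_low_sd")
})

test_that("greedy removal matches a brute-force pairwise oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    base <- rnorm(40)
    m <- dm(A = base + rnorm(40, sd = 0.1),
            B = base + rnorm(40, sd = 0.1),
            C = base + rnorm(40, sd = 0.1),
            D = rnorm(40), E = rnorm(40))
    thr <- 0.9
    out <- filter_correlated(m, thr)
    # oracle: simulate the documented rule directly from the full
    # correlation matrix
    cm <- abs(cor(m$values))
    kept <- character(0)
    for (nm in colnames(m$values)) {
      if (!length(kept) || all(cm[nm, kept] <= thr)) kept <- c(kept, nm)
    }
    expect_equal(colnames(out$matrix$values), kept)
    # survivors contain no pair above the threshold
    cs <- abs(cor(out$matrix$values)); diag(cs) <- 0
    expect_lt(max(cs), thr + 1e-12)
  }
})

test_that("the filter chain removes planted columns exactly and is idempotent", {
  d <- gen_descriptor_matrix(n = 100, p = 20, n_sparse = 3, n_constant = 2,
                             n_duplicated = 2, seed = 42)
  pr <- preprocess_descriptors(d$matrix)
  removed <- unlist(lapply(pr$reports, `[[`, "removed"), use.names = FALSE)
  expect_setequal(removed,
                  c(d$manifest$sparse, d$manifest$constant,
                    d$manifest$duplicated))
  # survivors preserve input order (subsequence)
  expect_equal(colnames(pr$matrix$values),
               intersect(colnames(d$matrix$values), colnames(pr$matrix$values)))
  # idempotence: second application removes nothing
  pr2 <- preprocess_descriptors(pr$matrix)
  expect_equal(pr2$matrix$values, pr$matrix$values)
  expect_length(unlist(lapply(pr2$reports, `[[`, "removed")), 0)
  # kept + removed partitions the original feature set
  expect_setequal(c(colnames(pr$matrix$values), removed),
                  colnames(d$matrix$values))
})
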