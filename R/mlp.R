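#' Multilayer perceptron classifier
#'
#' A small feed-forward network used as the stacking super learner and as
#' the protein-space fingerprint classifier: Tanh hidden layers, a 2-unit
#' softmax output, cross-entropy loss, and mini-batch stochastic gradient
#' descent with classical momentum, learning-rate annealing
#' (`lr_t = rate / (1 + rate_annealing * t)` over iterations `t`) and
#' optional input dropout.  Inputs are standardized internally
#' (constant columns are left centred at zero).
#'
#' @param x Numeric feature matrix (N x D).
#' @param y 0/1 class labels of length N; both classes must be present.
#' @param hidden Integer vector of hidden-layer sizes, e.g. `c(200, 400)`.
#' @param epochs Number of passes over the data (default 50).
#' @param rate Initial learning rate.
#' @param rate_annealing Annealing constant per SGD iteration.
#' @param momentum Classical momentum coefficient in `[0, 1)`.
#' @param input_dropout Probability of zeroing each input value during
#'   training (inverted dropout; inputs are rescaled by `1/(1-p)`).
#' @param l2 L2 weight penalty.
#' @param batch_size Mini-batch size (capped at N).
#' @param standardize Centre/scale inputs before training (default
#'   `TRUE`); disable for sparse count data where rare counts in
#'   near-constant columns would otherwise become high-leverage spikes.
#' @param seed Integer seed controlling initialization and batching.
#' @return An object of class `"hs_mlp"`.
#' @export
mlp <- function(x, y, hidden = c(32, 16), epochs = 50, rate = 0.05,
                rate_annealing = 1e-6, momentum = 0.9, input_dropout = 0,
                l2 = 1e-4, batch_size = 32, seed = 1, standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop_hs("x/y length mismatch")
  if (anyNA(x) || any(!is.finite(x))) stop_hs("non-finite values in x")
  if (length(unique(y)) < 2L) stop_hs("training labels contain a single class")
  if (!all(y %in% c(0L, 1L))) stop_hs("labels must be 0/1")
  check_prob(input_dropout, "input_dropout")
  stopifnot(epochs >= 1, length(hidden) >= 1)

  if (standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0] <- 1
  } else {
    center <- numeric(ncol(x))
    scale_ <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  sizes <- c(ncol(x), as.integer(hidden), 2L)
  L <- length(sizes) - 1L
  n <- nrow(xs)
  bs <- min(batch_size, n)
  Y <- cbind(1 - y, y)  # one-hot: column 1 = class 0, column 2 = class 1

  with_seed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    vW <- vector("list", L); vb <- vector("list", L)
    for (l in seq_len(L)) {
      s <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -s, s),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
      vW[[l]] <- W[[l]] * 0; vb[[l]] <- b[[l]] * 0
    }
    iter <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        A <- vector("list", L + 1L)
        A0 <- xs[idx, , drop = FALSE]
        if (input_dropout > 0) {
          mask <- matrix(stats::rbinom(length(A0), 1L, 1 - input_dropout),
                         nrow(A0)) / (1 - input_dropout)
          A0 <- A0 * mask
        }
        A[[1L]] <- A0
        for (l in seq_len(L - 1L)) {
          A[[l + 1L]] <- tanh(sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+"))
        }
        Z <- sweep(A[[L]] %*% W[[L]], 2, b[[L]], "+")
        Z <- Z - apply(Z, 1, max)
        P <- exp(Z); P <- P / rowSums(P)
        A[[L + 1L]] <- P

        iter <- iter + 1L
        lr <- rate / (1 + rate_annealing * iter)
        delta <- (P - Y[idx, , drop = FALSE]) / length(idx)
        for (l in rev(seq_len(L))) {
          dW <- crossprod(A[[l]], delta) + l2 * W[[l]]
          db <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(W[[l]])) * (1 - A[[l]]^2)
          }
          vW[[l]] <- momentum * vW[[l]] - lr * dW
          vb[[l]] <- momentum * vb[[l]] - lr * db
          W[[l]] <- W[[l]] + vW[[l]]
          b[[l]] <- b[[l]] + vb[[l]]
        }
      }
    }
    structure(list(W = W, b = b, center = center, scale = scale_,
                   sizes = sizes, feature_names = colnames(x),
                   config = list(hidden = hidden, epochs = epochs, rate = rate,
                                 rate_annealing = rate_annealing,
                                 momentum = momentum,
                                 input_dropout = input_dropout, l2 = l2,
                                 batch_size = bs, seed = seed,
                                 standardize = standardize)),
              class = "hs_mlp")
  })
}

#' Predict method for hs_mlp
#'
#' @param object A fitted [mlp()].
#' @param newdata Feature matrix with the training columns (matched by
#'   name when both are named).
#' @param ... Unused.
#' @return N x 2 matrix of class probabilities (columns `"0"` and `"1"`),
#'   each row summing to 1.
#' @export
predict.hs_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x))) {
    missing <- setdiff(object$feature_names, colnames(x))
    if (length(missing)) {
      stop_hs("missing features: %s", paste(missing, collapse = ", "))
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  if (ncol(x) != object$sizes[1L]) stop_hs("feature count mismatch")
  A <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  L <- length(object$W)
  for (l in seq_len(L - 1L)) {
    A <- tanh(sweep(A %*% object$W[[l]], 2, object$b[[l]], "+"))
  }
  Z <- sweep(A %*% object$W[[L]], 2, object$b[[L]], "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z); P <- P / rowSums(P)
  colnames(P) <- c("0", "1")
  P
}

#' @export
print.hs_mlp <- function(x, ...) {
  cat(sprintf("hs_mlp: layers %s, %d epochs, Tanh hidden / softmax output\n",
              paste(x$sizes, collapse = "-"), x$config$epochs))
  invisible(x)
}
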