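# Protein-space hit optimization: a deep network on substructure-count
# fingerprints, fused with per-complex interaction counts d_i into the
# ranking score beta = f(alpha) + d_i, filtered by a target-specific
# interaction-count window.

#' Target-specific interaction-count window
#'
#' Inclusive window `[d_min, d_max]` on the per-complex interaction count
#' used to keep only complexes whose contact richness matches the
#' target's binding-pocket profile (e.g. 9-12 for the CXCR4 pocket, 6-8
#' for the androgen receptor).
#'
#' @param d_min,d_max Non-negative integer bounds, `d_min <= d_max`.
#' @param target Optional target label carried into outputs.
#' @return A list of class `"threshold_window"`.
#' @export
threshold_window <- function(d_min, d_max, target = NULL) {
  d_min <- as.integer(d_min); d_max <- as.integer(d_max)
  if (is.na(d_min) || is.na(d_max) || d_min < 0L || d_max < d_min) {
    stop_hs("need 0 <= d_min <= d_max")
  }
  structure(list(d_min = d_min, d_max = d_max, target = target),
            class = "threshold_window")
}

#' @export
print.threshold_window <- function(x, ...) {
  cat(sprintf("threshold_window: [%d, %d]%s\n", x$d_min, x$d_max,
              if (is.null(x$target)) "" else paste0(" (", x$target, ")")))
  invisible(x)
}

#' Protein-space fingerprint classifier
#'
#' Trains the hit-optimization network on substructure-count
#' fingerprints: a (400, 200, 400, 2) architecture with Tanh activations
#' on the first three layers and a softmax output, trained for 50 epochs.
#' Hyperparameters (momentum, rate annealing, input-dropout ratio) are
#' selected by grid search under J-fold cross-validation (default
#' fivefold): the grid point with the highest mean CV AUC wins (ties go
#' to higher mean accuracy, then to grid order), and the final network is
#' refitted on all data at that point.
#'
#' @param x N x K matrix of non-negative integer substructure counts
#'   (e.g. from [fingerprint_matrix()] or [gen_fingerprint_dataset()]).
#' @param y 0/1 labels; both classes required.
#' @param hidden Hidden-layer sizes, default `c(400, 200, 400)`.
#' @param epochs Training epochs per fit (default 50).
#' @param folds Cross-validation folds (default 5).
#' @param grid Named list of hyperparameter vectors crossed into the
#'   search grid: `momentum`, `rate_annealing`, `input_dropout`.
#' @param rate,l2,batch_size Passed to [mlp()].
#' @param standardize Input standardization (default `FALSE`: counts are
#'   consumed on their raw scale, so near-constant background columns do
#'   not get inflated into high-leverage features).
#' @param seed Integer seed for folds and network initialization.
#' @return Object of class `"ps_net"` with components `model` (the
#'   refitted `hs_mlp`), `best` (chosen grid point), `cv` (per-grid-point
#'   mean CV AUC/accuracy), `cv_auc` (winning mean AUC) and `folds`.
#' @export
ps_net <- function(x, y, hidden = c(400, 200, 400), epochs = 50, folds = 5,
                   grid = list(momentum = 0.9, rate_annealing = 1e-6,
                               input_dropout = c(0, 0.1)),
                   rate = 0.05, l2 = 1e-3, batch_size = 32, seed = 1,
                   standardize = FALSE) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop_hs("x/y length mismatch")
  if (length(unique(y)) < 2L) stop_hs("labels contain a single class")
  if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop_hs("fingerprint counts must be non-negative integers")
  }
  if (!length(grid)) stop_hs("empty hyperparameter grid")
  gp <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  fa <- make_folds(nrow(x), folds, seed = child_seed(seed, 11L),
                   stratify_labels = y)
  cv <- data.frame(gp, mean_auc = NA_real_, mean_acc = NA_real_)
  for (g in seq_len(nrow(gp))) {
    aucs <- accs <- numeric(fa$J)
    for (j in seq_len(fa$J)) {
      tr <- fa$fold_of != j
      fit <- mlp(x[tr, , drop = FALSE], y[tr], hidden = hidden,
                 epochs = epochs, rate = rate,
                 rate_annealing = gp$rate_annealing[g] %||% 1e-6,
                 momentum = gp$momentum[g] %||% 0.9,
                 input_dropout = gp$input_dropout[g] %||% 0,
                 l2 = l2, batch_size = batch_size, standardize = standardize,
                 seed = child_seed(seed, 100L * g + j))
      p <- predict(fit, x[!tr, , drop = FALSE])[, "1"]
      aucs[j] <- auc_mw(y[!tr], p)
      accs[j] <- mean((p >= 0.5) == (y[!tr] == 1L))
    }
    cv$mean_auc[g] <- mean(aucs)
    cv$mean_acc[g] <- mean(accs)
  }
  # best mean AUC; ties -> higher accuracy -> first in grid order
  best_g <- order(-cv$mean_auc, -cv$mean_acc)[1L]
  final <- mlp(x, y, hidden = hidden, epochs = epochs, rate = rate,
               rate_annealing = gp$rate_annealing[best_g] %||% 1e-6,
               momentum = gp$momentum[best_g] %||% 0.9,
               input_dropout = gp$input_dropout[best_g] %||% 0,
               l2 = l2, batch_size = batch_size, standardize = standardize,
               seed = child_seed(seed, 7L))
  structure(list(model = final, best = as.list(gp[best_g, , drop = FALSE]),
                 cv = cv, cv_auc = cv$mean_auc[best_g], folds = fa,
                 seed = seed, call = match.call()),
            class = "ps_net")
}

#' Predict from the protein-space classifier
#'
#' @param object A fitted [ps_net()].
#' @param newdata Count matrix with the training columns.
#' @param ... Unused.
#' @return data.frame with columns `id`, `f_alpha` (positive-class
#'   probability) and `label` (`f_alpha >= 0.5`).
#' @export
predict.ps_net <- function(object, newdata, ...) {
  p <- predict(object$model, newdata)[, "1"]
  data.frame(id = rownames(newdata) %||% as.character(seq_along(p)),
             f_alpha = as.numeric(p), label = as.integer(p >= 0.5),
             stringsAsFactors = FALSE)
}

#' @export
print.ps_net <- function(x, ...) {
  cat(sprintf("ps_net: layers %s, CV AUC %.3f (J = %d)\n",
              paste(x$model$sizes, collapse = "-"), x$cv_auc, x$folds$J))
  cat("  best grid point:",
      paste(sprintf("%s = %g", names(x$best), unlist(x$best)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.ps_net <- function(object, ...) {
  print(object)
  cat("\nGrid search (mean CV AUC / accuracy):\n")
  print(object$cv, row.names = FALSE)
  invisible(object)
}

#' Hit-optimization score
#'
#' `beta = f_alpha + d_i`: the protein-space classifier's positive-class
#' probability plus the complex's interaction count.  Because
#' `f_alpha < 1`, beta orders candidates primarily by interaction count
#' and breaks ties within a count by classifier confidence.
#'
#' @param f_alpha Probability in `[0, 1]`.
#' @param d_i Non-negative integer interaction count.
#' @return Numeric beta (vectorized).
#' @export
score_beta <- function(f_alpha, d_i) {
  check_prob(f_alpha, "f_alpha")
  if (any(is.na(d_i)) || any(d_i < 0)) stop_hs("d_i must be >= 0")
  f_alpha + d_i
}

#' Rank hits by beta inside an interaction-count window
#'
#' Candidates are the predicted positives (when true labels are supplied
#' — the evaluation mode — only the true positives among them).  Each
#' candidate needs an interaction count; candidates inside the inclusive
#' window are ranked by beta descending, ties broken by higher `f_alpha`
#' then lexicographic id.  Candidates outside the window are listed after
#' the ranked block with `rank = NA` and `passed_window = FALSE`.
#'
#' @param predictions data.frame with columns `id` and `f_alpha` (e.g.
#'   from [predict.ps_net()]); predicted label is `f_alpha >= 0.5`.
#' @param profiles Named integer vector of `d_i` per id, or a data.frame
#'   with columns `id`, `d_i`.
#' @param window A [threshold_window()].
#' @param truth Optional named 0/1 vector of true labels enabling the
#'   true-positive evaluation mode.
#' @return data.frame of class `"ranked_hits"` with columns `id`,
#'   `f_alpha`, `d_i`, `beta`, `passed_window`, `rank`; mode and window
#'   are stored in attributes `mode` / `window`.
#' @export
rank_hits <- function(predictions, profiles, window, truth = NULL) {
  stopifnot(is.data.frame(predictions),
            all(c("id", "f_alpha") %in% names(predictions)),
            inherits(window, "threshold_window"))
  check_prob(predictions$f_alpha, "f_alpha")
  if (is.data.frame(profiles)) {
    profiles <- stats::setNames(profiles$d_i, profiles$id)
  }
  pred_pos <- predictions[predictions$f_alpha >= 0.5, , drop = FALSE]
  mode <- "deployment (predicted positives)"
  if (!is.null(truth)) {
    if (is.null(names(truth))) stop_hs("truth must be a named 0/1 vector")
    keep <- !is.na(truth[pred_pos$id]) & truth[pred_pos$id] == 1L
    pred_pos <- pred_pos[keep, , drop = FALSE]
    mode <- "evaluation (true positives)"
  }
  missing_prof <- setdiff(pred_pos$id, names(profiles))
  if (length(missing_prof)) {
    stop_hs("missing interaction profile for candidate(s): %s",
            paste(missing_prof, collapse = ", "))
  }
  d_i <- as.integer(profiles[pred_pos$id])
  beta <- score_beta(pred_pos$f_alpha, d_i)
  passed <- d_i >= window$d_min & d_i <= window$d_max
  out <- data.frame(id = pred_pos$id, f_alpha = pred_pos$f_alpha,
                    d_i = d_i, beta = beta, passed_window = passed,
                    rank = rep(NA_integer_, nrow(pred_pos)),
                    stringsAsFactors = FALSE)
  inw <- which(passed)
  ord <- inw[order(-out$beta[inw], -out$f_alpha[inw], out$id[inw])]
  out$rank[ord] <- seq_along(ord)
  out <- out[c(ord, setdiff(seq_len(nrow(out)), ord)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "mode") <- mode
  class(out) <- c("ranked_hits", "data.frame")
  out
}

#' @export
print.ranked_hits <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("ranked_hits (%s), window [%d, %d]: %d ranked, %d outside\n",
              attr(x, "mode"), w$d_min, w$d_max,
              sum(x$passed_window), sum(!x$passed_window)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
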