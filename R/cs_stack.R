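# Chemical-space stacked ensemble: base learners (random forest, extreme
# gradient boosting by default) produce out-of-fold class probabilities
# that train a neural-network super learner.

#' Cross-validation fold assignment
#'
#' Splits n instances into J approximately uniform folds (sizes differ by
#' at most 1), optionally stratified so every fold's class ratio stays
#' within one instance of the global ratio.  Deterministic given the
#' seed; the caller's RNG state is untouched.
#'
#' @param n Number of instances.
#' @param J Number of folds, `2 <= J <= n`.
#' @param seed Integer seed.
#' @param stratify_labels Optional 0/1 labels for stratification; each
#'   class must have at least J members.
#' @return An object of class `"fold_assignment"`: list with `n`, `J`,
#'   `fold_of` (fold ids 1..J) and `seed`.
#' @export
make_folds <- function(n, J, seed = 1, stratify_labels = NULL) {
  n <- as.integer(n); J <- as.integer(J)
  if (J < 2L || J > n) stop_hs("need 2 <= J <= n (got J=%d, n=%d)", J, n)
  fold_of <- integer(n)
  with_seed(seed, {
    if (is.null(stratify_labels)) {
      fold_of <- sample(rep_len(seq_len(J), n))
    } else {
      if (length(stratify_labels) != n) stop_hs("stratify_labels length != n")
      for (cl in unique(stratify_labels)) {
        idx <- which(stratify_labels == cl)
        if (length(idx) < J) {
          stop_hs("class %s has %d members, fewer than J = %d folds",
                  cl, length(idx), J)
        }
        # deal a shuffled class round-robin from a random starting fold
        start <- sample.int(J, 1L)
        folds <- ((start - 1L + seq_along(idx) - 1L) %% J) + 1L
        fold_of[sample(idx)] <- folds
      }
    }
  })
  structure(list(n = n, J = J, fold_of = fold_of, seed = seed,
                 stratified = !is.null(stratify_labels)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: n = %d, J = %d (sizes %s)%s\n", x$n, x$J,
              paste(tabulate(x$fold_of, x$J), collapse = "/"),
              if (x$stratified) ", stratified" else ""))
  invisible(x)
}

# ---- base-learner specifications -------------------------------------------

#' Base-learner specifications
#'
#' A base learner is a list with a `name`, a `fit(x, y)` function
#' returning a model and a `predict(model, x)` function returning
#' positive-class probabilities.  `learner_rf()` (random forest) and
#' `learner_xgb()` (extreme gradient boosting) are the defaults of the
#' chemical-space ensemble.  `learner_knn1()` memorizes its training rows
#' (1-nearest-neighbour) and exists to demonstrate that the out-of-fold
#' protocol leaks no labels; `learner_constant()` and
#' `learner_majority()` are degenerate references.
#'
#' @param ntree Number of random-forest trees.
#' @param nrounds,max_depth,eta Gradient-boosting rounds / tree depth /
#'   shrinkage.
#' @param p Constant probability emitted by `learner_constant()`.
#' @return A learner specification list.
#' @export
learner_rf <- function(ntree = 500) {
  list(name = "rf",
       fit = function(x, y) {
         randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                    ntree = ntree)
       },
       predict = function(model, x) {
         unname(stats::predict(model, x, type = "prob")[, "1"])
       })
}

#' @rdname learner_rf
#' @export
learner_xgb <- function(nrounds = 100, max_depth = 4, eta = 0.3) {
  list(name = "xgb",
       fit = function(x, y) {
         xgboost::xgb.train(
           params = list(objective = "binary:logistic", max_depth = max_depth,
                         eta = eta, nthread = 1),
           data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
           nrounds = nrounds, verbose = 0)
       },
       predict = function(model, x) {
         as.numeric(stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x))))
       })
}

#' @rdname learner_rf
#' @export
learner_constant <- function(p = 0.5) {
  list(name = "constant",
       fit = function(x, y) p,
       predict = function(model, x) rep(model, nrow(x)))
}

#' @rdname learner_rf
#' @export
learner_majority <- function() {
  list(name = "majority",
       fit = function(x, y) as.numeric(mean(y) >= 0.5),
       predict = function(model, x) rep(model, nrow(x)))
}

#' @rdname learner_rf
#' @export
learner_knn1 <- function() {
  list(name = "knn1",
       fit = function(x, y) list(x = as.matrix(x), y = y),
       predict = function(model, x) {
         x <- as.matrix(x)
         apply(x, 1, function(row) {
           d2 <- colSums((t(model$x) - row)^2)
           model$y[which.min(d2)]
         })
       })
}

default_learners <- function() list(learner_rf(), learner_xgb())

# ---- out-of-fold level-one data --------------------------------------------

#' Out-of-fold base-learner predictions (level-one data)
#'
#' For each fold j and each base learner t, trains t on all folds except
#' j and predicts fold j, so every instance receives exactly one
#' probability per learner from a model that never saw its fold.  The
#' resulting N x T matrix is the level-one training set of the super
#' learner.
#'
#' @param m A labelled [descriptor_matrix()].
#' @param learners List of learner specifications (see [learner_rf()]);
#'   default random forest + gradient boosting.
#' @param folds A [make_folds()] assignment with `folds$n == nrow(m)`.
#' @param seed Integer seed; each (learner, fold) fit draws a derived
#'   child seed.
#' @return An object of class `"level_one_data"`: list with `z` (N x T
#'   out-of-fold probabilities), `y`, `learner_names`, `folds`.
#' @export
fit_base_oof <- function(m, learners = default_learners(), folds,
                         seed = 1) {
  stopifnot(inherits(m, "descriptor_matrix"), inherits(folds, "fold_assignment"))
  if (is.null(m$labels)) stop_hs("descriptor matrix has no labels")
  if (folds$n != nrow(m$values)) stop_hs("fold assignment size mismatch")
  if (length(learners) < 1L) stop_hs("need at least one learner")
  x <- m$values; y <- m$labels
  T_ <- length(learners)
  z <- matrix(NA_real_, nrow(x), T_)
  names_ <- vapply(learners, `[[`, character(1), "name")
  colnames(z) <- names_
  for (t in seq_len(T_)) {
    for (j in seq_len(folds$J)) {
      tr <- folds$fold_of != j
      te <- !tr
      fit <- tryCatch(
        with_seed(child_seed(seed, t * 1000L + j),
                  learners[[t]]$fit(x[tr, , drop = FALSE], y[tr])),
        error = function(e) {
          stop_hs("base learner '%s' failed on fold %d: %s",
                  names_[t], j, conditionMessage(e))
        })
      z[te, t] <- learners[[t]]$predict(fit, x[te, , drop = FALSE])
    }
  }
  if (anyNA(z) || any(z < 0) || any(z > 1)) {
    stop_hs("out-of-fold predictions outside [0, 1]")
  }
  structure(list(z = z, y = y, learner_names = names_, folds = folds),
            class = "level_one_data")
}

#' @export
print.level_one_data <- function(x, ...) {
  cat(sprintf("level_one_data: %d instances x %d learners (%s), J = %d folds\n",
              nrow(x$z), ncol(x$z), paste(x$learner_names, collapse = ", "),
              x$folds$J))
  invisible(x)
}

#' Train the stacking super learner
#'
#' Fits the neural-network meta-model on level-one data: by default a
#' (200, 400, 2) architecture with Tanh hidden layers, softmax output and
#' 50 training epochs.  The output layer is a 2-way softmax so the
#' meta-model emits class probabilities summing to one.
#'
#' @param l1 A `level_one_data` object from [fit_base_oof()].
#' @param hidden Hidden-layer sizes (default `c(200, 400)`).
#' @param epochs Training epochs (default 50).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [mlp()].
#' @return A fitted `"hs_mlp"` super learner.
#' @export
fit_super_learner <- function(l1, hidden = c(200, 400), epochs = 50,
                              seed = 1, ...) {
  stopifnot(inherits(l1, "level_one_data"))
  if (anyNA(l1$z) || any(!is.finite(l1$z))) stop_hs("non-finite level-one data")
  if (length(unique(l1$y)) < 2L) stop_hs("level-one labels contain one class")
  mlp(l1$z, l1$y, hidden = hidden, epochs = epochs, seed = seed, ...)
}

# ---- the fitted stacked model ----------------------------------------------

#' Chemical-space stacked ensemble
#'
#' Fits the two-tier hit-identification model: J-fold out-of-fold
#' probabilities from the base learners (tier 0; random forest and
#' extreme gradient boosting by default) become the level-one inputs of a
#' neural-network super learner (tier 1), and the base learners are then
#' refitted on the full data for deployment.
#'
#' @param x Numeric feature matrix with named columns, or a
#'   [descriptor_matrix()].
#' @param y 0/1 labels (ignored when `x` is a labelled descriptor
#'   matrix).
#' @param learners Base-learner specifications; see [learner_rf()].
#' @param folds Number of cross-validation folds J (default 10).
#' @param hidden,epochs Super-learner architecture and training length.
#' @param seed Integer seed governing folds, learner fits and network
#'   initialization.
#' @param ... Passed to [fit_super_learner()].
#' @return An object of class `"cs_stack"` with components `base_models`,
#'   `super_model`, `level_one`, `learner_names`, `feature_names`,
#'   `oof_metrics` (per-learner out-of-fold [classification_metrics()]),
#'   `entropy` (ensemble diversity of the base learners' out-of-fold hard
#'   predictions) and `seed`.
#' @seealso [predict.cs_stack()], [summary.cs_stack()]
#' @examples
#' \donttest{
#' d <- gen_descriptor_matrix(n = 120, p = 12, class_sep = 2, seed = 7)
#' fit <- cs_stack(d$matrix, folds = 5, hidden = c(8, 4), seed = 7)
#' predict(fit, d$matrix$values[1:3, ])
#' }
#' @export
cs_stack <- function(x, y = NULL, learners = default_learners(), folds = 10,
                     hidden = c(200, 400), epochs = 50, seed = 1, ...) {
  if (inherits(x, "descriptor_matrix")) {
    m <- x
    if (!is.null(y)) m$labels <- as.integer(y)
  } else {
    m <- descriptor_matrix(as.matrix(x), labels = y)
  }
  if (is.null(m$labels)) stop_hs("labels are required to fit cs_stack")
  fa <- make_folds(nrow(m$values), folds, seed = child_seed(seed, 1L),
                   stratify_labels = m$labels)
  l1 <- fit_base_oof(m, learners, fa, seed = child_seed(seed, 2L))
  super <- fit_super_learner(l1, hidden = hidden, epochs = epochs,
                             seed = child_seed(seed, 3L), ...)
  base_models <- lapply(seq_along(learners), function(t) {
    with_seed(child_seed(seed, 100L + t),
              learners[[t]]$fit(m$values, m$labels))
  })
  oof_metrics <- lapply(seq_len(ncol(l1$z)), function(t) {
    classification_metrics(l1$y, l1$z[, t])
  })
  names(oof_metrics) <- l1$learner_names
  obj <- list(
    base_models = base_models,
    learners = learners,
    super_model = super,
    level_one = l1,
    learner_names = l1$learner_names,
    feature_names = colnames(m$values),
    oof_metrics = oof_metrics,
    entropy = ensemble_entropy((l1$z >= 0.5) * 1L, l1$y),
    folds = fa,
    seed = seed,
    call = match.call()
  )
  class(obj) <- "cs_stack"
  obj
}

#' Predict from a stacked ensemble
#'
#' Runs the deployment path: full-data base models produce probabilities
#' that the super learner combines.  Feature columns are aligned to the
#' training order by name; missing or extra features are an error.  The
#' predicted label is 1 when the positive-class probability is `>= 0.5`
#' (ties are called positive).
#'
#' @param object A fitted [cs_stack()].
#' @param newdata Feature matrix with the training feature names.
#' @param ... Unused.
#' @return A data.frame with columns `id`, `proba`, `label`.
#' @export
predict.cs_stack <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "descriptor_matrix")) newdata$values else as.matrix(newdata)
  if (!is.null(colnames(x))) {
    missing <- setdiff(object$feature_names, colnames(x))
    extra <- setdiff(colnames(x), object$feature_names)
    if (length(missing) || length(extra)) {
      stop_hs("feature mismatch; missing: [%s], extra: [%s]",
              paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    }
    x <- x[, object$feature_names, drop = FALSE]
  } else if (ncol(x) != length(object$feature_names)) {
    stop_hs("feature count mismatch")
  }
  z <- vapply(seq_along(object$base_models), function(t) {
    object$learners[[t]]$predict(object$base_models[[t]], x)
  }, numeric(nrow(x)))
  z <- matrix(z, nrow = nrow(x))
  colnames(z) <- object$learner_names
  proba <- predict(object$super_model, z)[, "1"]
  data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
             proba = as.numeric(proba),
             label = as.integer(proba >= 0.5),
             stringsAsFactors = FALSE)
}

#' @export
print.cs_stack <- function(x, ...) {
  cat("Chemical-space stacked ensemble\n")
  cat(sprintf("  base learners: %s (J = %d folds)\n",
              paste(x$learner_names, collapse = ", "), x$folds$J))
  cat(sprintf("  super learner: layers %s\n",
              paste(x$super_model$sizes, collapse = "-")))
  cat(sprintf("  training instances: %d, features: %d\n",
              nrow(x$level_one$z), length(x$feature_names)))
  invisible(x)
}

#' @export
summary.cs_stack <- function(object, ...) {
  cat("Chemical-space stacked ensemble\n\n")
  cat("Out-of-fold base-learner performance:\n")
  for (nm in names(object$oof_metrics)) {
    m <- object$oof_metrics[[nm]]
    cat(sprintf("  %-10s AUC %.3f  acc %.3f  Se %.3f  Sp %.3f  BCR %.3f\n",
                nm, m$auc, m$accuracy, m$sensitivity, m$specificity, m$bcr))
  }
  cat(sprintf("\nEnsemble diversity entropy E = %.3f\n", object$entropy))
  sm <- classification_metrics(object$level_one$y,
                               predict(object$super_model,
                                       object$level_one$z)[, "1"])
  cat("Super learner on level-one data:\n")
  print(sm)
  invisible(object)
}
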