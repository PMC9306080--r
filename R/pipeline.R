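# End-to-end orchestration.  Every stage consumes and produces plain
# files (CSV/JSON), so runs are restartable and each artifact is
# reproducible from the manifest alone.

#' Default run configuration
#'
#' All thresholds default to the pipeline's canonical values: potency
#' cutoff 0.05 µM; filter chain 0.85 / 0.03 / 0.90; 10 chemical-space
#' folds and 5 protein-space folds; 50 training epochs; interaction
#' window 9-12 (the CXCR4-style pocket profile; use 6-8 for an
#' androgen-receptor-style pocket).
#'
#' @param ... Overrides merged over the defaults (named as in the
#'   returned list).
#' @return A nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    label_cutoff_uM = 0.05,
    filters = list(max_zero_frac = 0.85, min_sd = 0.03, max_abs_rho = 0.90),
    split = list(mode = "holdout", eval_fraction = 0.10),  # or mode = "7:3"
    cs = list(folds = 10, hidden = c(200, 400), epochs = 50),
    ps = list(folds = 5, hidden = c(400, 200, 400), epochs = 50,
              grid = list(momentum = 0.9, rate_annealing = 1e-6,
                          input_dropout = c(0, 0.1))),
    window = c(9, 12),
    seed = 1
  )
  overrides <- list(...)
  utils::modifyList(cfg, overrides)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [default_config()], merged over the
#'   defaults so a minimal file only needs paths.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_hs("config not found: %s", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

split_indices <- function(n, split, labels, seed) {
  frac <- if (identical(split$mode, "7:3")) 0.3 else split$eval_fraction %||% 0.1
  with_seed(seed, {
    ev <- sort(sample.int(n, max(1L, round(frac * n))))
  })
  list(train = setdiff(seq_len(n), ev), eval = ev)
}

metrics_as_list <- function(m) {
  m[c("accuracy", "sensitivity", "specificity", "auc", "bcr", "n")]
}

#' Run the two-stage screening pipeline end to end
#'
#' Chains descriptor preprocessing, the chemical-space stacked ensemble,
#' the protein-space fingerprint classifier and beta ranking, writing all
#' artifacts plus a JSON run manifest into `outdir`.
#'
#' @param descriptors Labelled [descriptor_matrix()] or path to a
#'   descriptor CSV (first column id) with `label_column`.
#' @param fingerprints Count matrix (rows named by molecule id) or path
#'   to a fingerprint CSV.
#' @param profiles Named `d_i` vector, data.frame (`id`, `d_i`), or path
#'   to a profile CSV.
#' @param config Configuration from [default_config()] / [read_config()].
#' @param label_column Label column name for a descriptor CSV.
#' @param outdir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param evaluation_mode Rank only true positives (the evaluation
#'   convention); `FALSE` ranks all predicted positives.
#' @return List with `cs_fit`, `ps_fit`, `cs_metrics`, `ps_metrics`
#'   (evaluation-split [classification_metrics()]), `ranked`
#'   ([rank_hits()] output) and `manifest`.
#' @export
run_screen <- function(descriptors, fingerprints, profiles,
                       config = default_config(), label_column = "label",
                       outdir = NULL, evaluation_mode = TRUE) {
  if (is.character(descriptors)) {
    descriptors <- read_descriptor_csv(descriptors, label_column = label_column)
  }
  stopifnot(inherits(descriptors, "descriptor_matrix"))
  if (is.null(descriptors$labels)) stop_hs("descriptors must carry labels")
  if (is.character(fingerprints)) {
    fpm <- read_descriptor_csv(fingerprints)
    fingerprints <- fpm$values
  }
  if (is.character(profiles)) {
    pr <- utils::read.csv(profiles, stringsAsFactors = FALSE)
    profiles <- stats::setNames(as.integer(pr$d_i), pr$id)
  }
  if (is.data.frame(profiles)) {
    profiles <- stats::setNames(as.integer(profiles$d_i), profiles$id)
  }
  seed <- config$seed %||% 1

  prep <- preprocess_descriptors(
    descriptors,
    max_zero_frac = config$filters$max_zero_frac,
    min_sd = config$filters$min_sd,
    max_abs_rho = config$filters$max_abs_rho)
  m <- prep$matrix
  ids <- rownames(m$values)
  sp <- split_indices(nrow(m$values), config$split, m$labels,
                      child_seed(seed, 31L))

  cs_fit <- cs_stack(descriptor_matrix(m$values[sp$train, , drop = FALSE],
                                       labels = m$labels[sp$train]),
                     folds = config$cs$folds, hidden = config$cs$hidden,
                     epochs = config$cs$epochs, seed = child_seed(seed, 32L))
  cs_pred <- predict(cs_fit, m$values[sp$eval, , drop = FALSE])
  cs_metrics <- classification_metrics(m$labels[sp$eval], cs_pred$proba)

  fp_ids <- rownames(fingerprints)
  if (is.null(fp_ids) || !all(ids %in% fp_ids)) {
    stop_hs("fingerprints must cover every descriptor id")
  }
  missing_prof <- setdiff(ids[sp$eval], names(profiles))
  if (length(missing_prof)) {
    stop_hs("rank stage: missing interaction profiles for %s",
            paste(utils::head(missing_prof, 5), collapse = ", "))
  }
  ps_fit <- ps_net(fingerprints[ids[sp$train], , drop = FALSE],
                   m$labels[sp$train],
                   hidden = config$ps$hidden, epochs = config$ps$epochs,
                   folds = config$ps$folds, grid = config$ps$grid,
                   seed = child_seed(seed, 33L))
  ps_pred <- predict(ps_fit, fingerprints[ids[sp$eval], , drop = FALSE])
  ps_metrics <- classification_metrics(m$labels[sp$eval], ps_pred$f_alpha)

  window <- threshold_window(config$window[1], config$window[2])
  truth <- if (evaluation_mode) {
    stats::setNames(m$labels[sp$eval], ids[sp$eval])
  } else NULL
  ranked <- rank_hits(ps_pred, profiles, window, truth = truth)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hitstack")),
    seed = seed,
    filters = config$filters,
    split = config$split,
    window = c(window$d_min, window$d_max),
    cs = config$cs, ps = list(folds = config$ps$folds,
                              hidden = config$ps$hidden,
                              epochs = config$ps$epochs,
                              best_grid_point = ps_fit$best),
    removed_features = lapply(prep$reports, `[[`, "removed"),
    n_train = length(sp$train), n_eval = length(sp$eval),
    mode = attr(ranked, "mode"))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_descriptor_csv(m, file.path(outdir, "filtered_descriptors.csv"))
    utils::write.csv(cs_pred, file.path(outdir, "cs_predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ranked),
                     file.path(outdir, "ranked_hits.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(cs = metrics_as_list(cs_metrics), ps = metrics_as_list(ps_metrics)),
      file.path(outdir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(cs_fit = cs_fit, ps_fit = ps_fit, cs_metrics = cs_metrics,
       ps_metrics = ps_metrics, ranked = ranked, manifest = manifest)
}

#' Standalone base-learner baselines
#'
#' Trains each learner on the training split alone and evaluates it on
#' the held-out split with the same metrics as the stacked ensemble, for
#' side-by-side comparison.
#'
#' @param x Feature matrix, `y` 0/1 labels.
#' @param y Labels.
#' @param learners Learner specifications (default RF + XGB).
#' @param split,seed Evaluation split (as in [default_config()]) and
#'   seed.
#' @return Named list of [classification_metrics()] per learner.
#' @export
run_baselines <- function(x, y, learners = default_learners(),
                          split = list(mode = "holdout", eval_fraction = 0.1),
                          seed = 1) {
  x <- if (inherits(x, "descriptor_matrix")) x$values else as.matrix(x)
  sp <- split_indices(nrow(x), split, y, child_seed(seed, 41L))
  out <- list()
  for (t in seq_along(learners)) {
    fit <- with_seed(child_seed(seed, 42L + t),
                     learners[[t]]$fit(x[sp$train, , drop = FALSE],
                                       y[sp$train]))
    p <- learners[[t]]$predict(fit, x[sp$eval, , drop = FALSE])
    out[[learners[[t]]$name]] <- classification_metrics(y[sp$eval], p)
  }
  out
}
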