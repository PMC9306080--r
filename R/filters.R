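# Descriptor preprocessing: three-stage filter chain applied before any
# model sees the data.  Stage order is fixed (sparse -> low SD ->
# correlated) so that zero-variance columns are gone before correlations
# are computed.

filter_report <- function(stage, removed, threshold, kept_count) {
  structure(list(stage = stage, removed = removed,
                 threshold = threshold, kept_count = kept_count),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter '%s' (threshold %g): removed %d, kept %d\n",
              x$stage, x$threshold, length(x$removed), x$kept_count))
  invisible(x)
}

drop_columns <- function(m, removed, stage, threshold) {
  keep <- setdiff(colnames(m$values), removed)
  out <- descriptor_matrix(m$values[, keep, drop = FALSE], labels = m$labels)
  list(matrix = out,
       report = filter_report(stage, removed, threshold, length(keep)))
}

#' Remove sparse descriptors
#'
#' Drops columns whose fraction of exact zeros is strictly greater than
#' `max_zero_frac` (default 0.85, i.e. "more than 85% zeros").  Values
#' are not rounded before counting.
#'
#' @param m A [descriptor_matrix()].
#' @param max_zero_frac Maximum tolerated zero fraction, in `[0, 1]`.
#' @return A list with elements `matrix` (the filtered
#'   [descriptor_matrix()]) and `report` (a `filter_report`).
#' @export
filter_sparse <- function(m, max_zero_frac = 0.85) {
  stopifnot(inherits(m, "descriptor_matrix"))
  check_prob(max_zero_frac, "max_zero_frac")
  zf <- colMeans(m$values == 0)
  drop_columns(m, colnames(m$values)[zf > max_zero_frac],
               "sparse", max_zero_frac)
}

#' Remove low-variability descriptors
#'
#' Drops columns whose sample standard deviation (n-1 denominator) is
#' strictly less than `min_sd`.  The default 0.03 reads the conventional
#' "SD below 3%" rule as an absolute threshold on raw descriptor values;
#' set `relative = TRUE` to use the coefficient of variation
#' (SD / |mean|) instead.
#'
#' @param m A [descriptor_matrix()].
#' @param min_sd Minimum standard deviation.
#' @param relative If `TRUE`, compare `min_sd` against SD/|mean|.
#' @return A list with `matrix` and `report` as in [filter_sparse()].
#' @export
filter_low_sd <- function(m, min_sd = 0.03, relative = FALSE) {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (!is.numeric(min_sd) || min_sd < 0) stop_hs("min_sd must be >= 0")
  sds <- apply(m$values, 2, stats::sd)
  if (relative) {
    mu <- abs(colMeans(m$values))
    sds <- ifelse(mu > 0, sds / mu, 0)
  }
  drop_columns(m, colnames(m$values)[sds < min_sd], "low_sd", min_sd)
}

#' Remove correlated descriptors
#'
#' Scans columns left to right; a column is dropped when its absolute
#' Pearson correlation with any *surviving* earlier column is strictly
#' greater than `max_abs_rho` (default 0.90).  The earlier column is
#' kept, so a removed column can never trigger further removals, and the
#' survivor set contains no pair above the threshold.
#'
#' @param m A [descriptor_matrix()] with no zero-variance columns (run
#'   [filter_low_sd()] first).
#' @param max_abs_rho Correlation threshold in `[0, 1]`.
#' @return A list with `matrix` and `report` as in [filter_sparse()].
#' @export
filter_correlated <- function(m, max_abs_rho = 0.90) {
  stopifnot(inherits(m, "descriptor_matrix"))
  check_prob(max_abs_rho, "max_abs_rho")
  sds <- apply(m$values, 2, stats::sd)
  if (any(sds == 0)) {
    stop_hs("zero-variance column(s) (%s): run filter_low_sd first",
            paste(colnames(m$values)[sds == 0], collapse = ", "))
  }
  p <- ncol(m$values)
  if (p < 2L) return(drop_columns(m, character(0), "correlated", max_abs_rho))
  cm <- abs(stats::cor(m$values))
  kept <- integer(0)
  removed <- character(0)
  for (j in seq_len(p)) {
    if (length(kept) && any(cm[j, kept] > max_abs_rho)) {
      removed <- c(removed, colnames(m$values)[j])
    } else {
      kept <- c(kept, j)
    }
  }
  drop_columns(m, removed, "correlated", max_abs_rho)
}

#' Descriptor filter chain
#'
#' Applies [filter_sparse()], [filter_low_sd()] and [filter_correlated()]
#' in that fixed order.  The chain is idempotent: a second application
#' removes nothing.
#'
#' @param m A [descriptor_matrix()].
#' @param max_zero_frac,min_sd,sd_relative,max_abs_rho Stage thresholds;
#'   see the individual filters.
#' @return A list with `matrix` (filtered [descriptor_matrix()]) and
#'   `reports` (list of three `filter_report`s named `sparse`, `low_sd`,
#'   `correlated`).
#' @export
preprocess_descriptors <- function(m, max_zero_frac = 0.85, min_sd = 0.03,
                                   sd_relative = FALSE, max_abs_rho = 0.90) {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (ncol(m$values) == 0L) stop_hs("descriptor matrix has no columns")
  s1 <- filter_sparse(m, max_zero_frac)
  s2 <- filter_low_sd(s1$matrix, min_sd, relative = sd_relative)
  s3 <- filter_correlated(s2$matrix, max_abs_rho)
  list(matrix = s3$matrix,
       reports = list(sparse = s1$report, low_sd = s2$report,
                      correlated = s3$report))
}
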