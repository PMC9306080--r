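#' Descriptor matrix container
#'
#' A light wrapper around a numeric instance-by-feature matrix with
#' molecule ids as row names, descriptor names as column names and an
#' optional binary label vector.
#'
#' @param values Numeric matrix (rows = molecules, columns = descriptors)
#'   with unique row and column names.
#' @param labels Optional 0/1 integer vector of length `nrow(values)`.
#' @return An object of class `"descriptor_matrix"` with elements
#'   `values` and `labels`.
#' @export
descriptor_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_hs("descriptor values must be numeric")
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("mol", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    if (ncol(values) == 0L) {
      colnames(values) <- character(0)   # empty survivor set is legal
    } else {
      stop_hs("descriptor columns must be named")
    }
  }
  if (anyDuplicated(rownames(values))) stop_hs("duplicate molecule ids")
  if (anyDuplicated(colnames(values))) stop_hs("duplicate feature names")
  if (any(!is.finite(values))) stop_hs("descriptor values must be finite")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values)) stop_hs("labels length != row count")
    if (!all(labels %in% c(0L, 1L))) stop_hs("labels must be 0/1")
  }
  structure(list(values = values, labels = labels),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("descriptor_matrix: %d molecules x %d descriptors%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(" (labels: %d positive / %d negative)",
                        sum(x$labels == 1L), sum(x$labels == 0L))))
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

#' Read a descriptor matrix from CSV
#'
#' Expects a header row, the molecule id in the first column and one
#' numeric descriptor per remaining column.  Non-numeric or missing cells
#' are an error naming the offending row and column.
#'
#' @param path CSV file path.
#' @param label_column Optional name of a 0/1 label column to split out.
#' @return A [descriptor_matrix()].
#' @export
read_descriptor_csv <- function(path, label_column = NULL) {
  if (!file.exists(path)) stop_hs("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop_hs("empty or id-only CSV: %s", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop_hs("duplicate molecule ids in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  raw_names <- names(df)[-1L]            # before [.data.frame dedupes them
  if (anyDuplicated(raw_names)) {
    stop_hs("duplicate feature names in %s: %s", path,
            paste(unique(raw_names[duplicated(raw_names)]), collapse = ", "))
  }
  feat <- df[-1L]
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(feat)) {
      stop_hs("label column '%s' not found in %s", label_column, path)
    }
    labels <- feat[[label_column]]
    feat[[label_column]] <- NULL
  }
  for (j in seq_along(feat)) {
    col <- feat[[j]]
    if (all(is.na(col))) stop_hs("column '%s' is entirely empty", names(feat)[j])
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop_hs("non-numeric value in column '%s', row id '%s' (value '%s')",
              names(feat)[j], ids[bad[1L]], as.character(col[bad[1L]]))
    }
    feat[[j]] <- num
  }
  m <- as.matrix(feat)
  rownames(m) <- ids
  descriptor_matrix(m, labels = labels)
}

#' Write a descriptor matrix to CSV
#'
#' Full-precision round-trip companion of [read_descriptor_csv()].
#'
#' @param m A [descriptor_matrix()].
#' @param path Output CSV path.
#' @param label_column Column name used for labels when present.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(m, path, label_column = "label") {
  stopifnot(inherits(m, "descriptor_matrix"))
  df <- data.frame(id = rownames(m$values), check.names = FALSE)
  vals <- as.data.frame(m$values, check.names = FALSE)
  # format() at 17 significant digits keeps doubles exact across the round trip
  for (j in seq_along(vals)) vals[[j]] <- formatC(vals[[j]], digits = 17, format = "g")
  df <- cbind(df, vals)
  if (!is.null(m$labels)) df[[label_column]] <- m$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
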