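#' Read molecules from a SMILES table or SDF
#'
#' A SMILES table is a comma- or whitespace-delimited text file with a
#' header naming at least `id` and `smiles`, and optionally `ic50_uM` and
#' `label`.  An SDF is standard V2000; IC50 values are read from a named
#' data field.  Structures that fail to parse are collected as record
#' level failures (the run continues); an empty file is an error.
#'
#' @param path Input file.
#' @param format `"smiles_table"` or `"sdf"`.
#' @param ic50_property SDF data field holding the IC50 in micromolar
#'   (default `"IC50_uM"`).
#' @return A data.frame with columns `id`, `smiles`, `ic50` (µM, `NA`
#'   when absent) and `label` (`NA` when absent), one row per
#'   successfully parsed molecule.  Parse failures are attached as a
#'   data.frame in `attr(, "failures")`.
#' @export
read_molecules <- function(path, format = c("smiles_table", "sdf"),
                           ic50_property = "IC50_uM") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_hs("file not found: %s", path)
  if (format == "smiles_table") {
    read_smiles_table(path)
  } else {
    read_sdf_molecules(path, ic50_property)
  }
}

smiles_is_valid <- function(smiles) {
  # OpenBabel returns an empty string for structures it cannot parse
  vapply(smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMILES", "CAN", source = s),
                    error = function(e) "")
    nzchar(trimws(out))
  }, logical(1), USE.NAMES = FALSE)
}

read_smiles_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_hs("empty molecule file: %s", path)
  sep <- if (grepl(",", lines[[1L]])) "," else ""
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("id", "smiles") %in% names(df))) {
    stop_hs("SMILES table must have 'id' and 'smiles' columns: %s", path)
  }
  if (nrow(df) == 0L) stop_hs("empty molecule file: %s", path)
  if (anyDuplicated(df$id)) {
    stop_hs("duplicate molecule ids: %s",
            paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  ok <- smiles_is_valid(df$smiles)
  failures <- data.frame(id = as.character(df$id[!ok]),
                         reason = rep("unparsable SMILES", sum(!ok)),
                         stringsAsFactors = FALSE)
  out <- data.frame(
    id     = as.character(df$id[ok]),
    smiles = as.character(df$smiles[ok]),
    ic50   = if ("ic50_um" %in% names(df)) as.numeric(df$ic50_um[ok]) else NA_real_,
    label  = if ("label" %in% names(df)) as.integer(df$label[ok]) else NA_integer_,
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$ic50) & out$ic50 <= 0)) stop_hs("IC50 values must be positive")
  if (nrow(failures)) {
    message(sprintf("read_molecules: %d record(s) failed to parse (%s)",
                    nrow(failures), paste(failures$id, collapse = ", ")))
  }
  attr(out, "failures") <- failures
  out
}

read_sdf_molecules <- function(path, ic50_property) {
  sdf <- ChemmineR::read.SDFset(path)
  if (length(sdf) == 0L) stop_hs("empty SDF file: %s", path)
  valid <- ChemmineR::validSDF(sdf)
  ids <- ChemmineR::sdfid(sdf)
  failures <- data.frame(id = as.character(ids[!valid]),
                         reason = rep("invalid SDF block", sum(!valid)),
                         stringsAsFactors = FALSE)
  sdf <- sdf[valid]
  ids <- ids[valid]
  smiles <- vapply(seq_along(sdf), function(i) {
    blk <- paste(ChemmineR::sdf2str(sdf[[i]]), collapse = "\n")
    out <- tryCatch(ChemmineOB::convertFormat("SDF", "SMILES", source = blk),
                    error = function(e) "")
    strsplit(trimws(out), "[\t ]")[[1]][1] %||% ""
  }, character(1))
  ic50 <- vapply(seq_along(sdf), function(i) {
    db <- ChemmineR::datablock(sdf[[i]])
    if (ic50_property %in% names(db)) as.numeric(db[[ic50_property]]) else NA_real_
  }, numeric(1))
  out <- data.frame(id = as.character(ids), smiles = smiles, ic50 = ic50,
                    label = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(failures)) {
    message(sprintf("read_molecules: %d record(s) failed to parse (%s)",
                    nrow(failures), paste(failures$id, collapse = ", ")))
  }
  attr(out, "failures") <- failures
  out
}

#' Label molecules by potency
#'
#' Assigns the inhibitor class from measured potency: `label = 1` iff
#' `ic50 < cutoff` (strict), else 0.  The default cutoff is 0.05 µM.
#' When the input already carries labels they must agree with the
#' potency-derived ones; a mismatch is an error rather than a silent
#' preference for either source.
#'
#' @param records Molecule data.frame from [read_molecules()].
#' @param cutoff Potency cutoff in µM (default 0.05).
#' @return The records with the `label` column filled in.
#' @export
label_by_potency <- function(records, cutoff = 0.05) {
  stopifnot(is.data.frame(records))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop_hs("cutoff must be a positive scalar (micromolar)")
  }
  if (anyNA(records$ic50)) {
    stop_hs("missing IC50 for record(s): %s",
            paste(records$id[is.na(records$ic50)], collapse = ", "))
  }
  derived <- as.integer(records$ic50 < cutoff)
  if ("label" %in% names(records) && any(!is.na(records$label))) {
    given <- !is.na(records$label)
    if (any(records$label[given] != derived[given])) {
      bad <- records$id[given][records$label[given] != derived[given]]
      stop_hs("given labels disagree with IC50-derived labels for: %s",
              paste(bad, collapse = ", "))
    }
  }
  records$label <- derived
  records
}
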