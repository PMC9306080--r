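# Substructure-count fingerprints for ligands.  The protein-space
# classifier consumes a fixed library of 4860 SMARTS substructure
# queries, matching the cardinality of the Klekota-Roth pattern set used
# with this fingerprint family.  The genuine Klekota-Roth SMARTS list is
# not redistributable here, so the package ships a *synthetic* library
# (see build_substructure_library) of exactly 4860 deterministic, valid
# SMARTS patterns with the same interface and count semantics.

KR_LIBRARY_SIZE <- 4860L

#' Build the synthetic substructure library
#'
#' Deterministically enumerates exactly 4860 distinct, syntactically
#' valid SMARTS patterns: all element chains of length 1-4 over
#' {C, N, O, S, P, F, Cl, Br} (4680), benzene and cyclohexane cores with
#' every length-1 or length-2 substituent (144), and doubly substituted
#' benzenes (36).  The enumeration is a pure function, so two calls (or
#' two machines) always produce the identical ordered pattern list.
#' This is a synthetic stand-in for the Klekota-Roth pattern list, which
#' cannot be shipped; cardinality and usage are identical.
#'
#' @return Character vector of 4860 SMARTS patterns in canonical order.
#' @export
build_substructure_library <- function() {
  atoms <- c("C", "N", "O", "S", "P", "F", "Cl", "Br")
  chains <- character(0)
  for (len in 1:4) {
    grid <- do.call(expand.grid,
                    c(rep(list(atoms), len), stringsAsFactors = FALSE))
    # vary the last position fastest so short prefixes group together
    chains <- c(chains, apply(grid[, rev(seq_len(len)), drop = FALSE],
                              1, paste0, collapse = ""))
  }
  subs <- c(atoms, as.vector(outer(atoms, atoms, paste0)))
  ring_single <- as.vector(outer(subs, c("c1ccccc1", "C1CCCCC1"), paste0))
  a6 <- c("C", "N", "O", "S", "P", "F")
  ring_double <- as.vector(t(outer(a6, a6,
                                   function(a, b) paste0(a, "c1ccccc1", b))))
  pats <- c(chains, ring_single, ring_double)
  stopifnot(length(pats) == KR_LIBRARY_SIZE, !anyDuplicated(pats))
  pats
}

#' Load the packaged substructure library
#'
#' Reads the pattern file shipped with the package (or a user-supplied
#' one: plain text, one SMARTS per line, `#` comments allowed) and
#' validates its size and uniqueness.  The packaged file is additionally
#' checked against the in-code enumeration so a corrupted installation is
#' caught at load time.
#'
#' @param path Optional path to an alternative pattern file.
#' @return An object of class `"substructure_library"`: list with
#'   `patterns` (character vector, stable 1-based indices) and `source`.
#' @export
load_library <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "synthetic_substructure_library.smarts",
                        package = "hitstack")
    if (!nzchar(path)) stop_hs("packaged substructure library is missing")
  }
  if (!file.exists(path)) stop_hs("pattern file not found: %s", path)
  pats <- readLines(path, warn = FALSE)
  pats <- trimws(pats)
  pats <- pats[nzchar(pats) & !startsWith(pats, "#")]
  if (length(pats) == 0L) stop_hs("pattern file is empty: %s", path)
  if (anyDuplicated(pats)) stop_hs("duplicate patterns in %s", path)
  if (packaged) {
    if (length(pats) != KR_LIBRARY_SIZE) {
      stop_hs("packaged library is corrupt: %d patterns (expected %d)",
              length(pats), KR_LIBRARY_SIZE)
    }
    if (!identical(pats, build_substructure_library())) {
      stop_hs("packaged library does not match the canonical enumeration")
    }
  }
  structure(list(patterns = pats, source = path,
                 version = "synthetic-1"),
            class = "substructure_library")
}

#' @export
print.substructure_library <- function(x, ...) {
  cat(sprintf("substructure_library: %d SMARTS patterns (%s)\n",
              length(x$patterns), x$version))
  invisible(x)
}

#' @export
length.substructure_library <- function(x) length(x$patterns)

#' Substructure-count fingerprint of one molecule
#'
#' Counts, for every library pattern, the number of unique substructure
#' matches in the molecule (symmetry-equivalent matches collapsed), or
#' their 0/1 indicator in binary mode.  `binary` is always
#' `(count > 0)`, so the two modes are consistent by construction.
#'
#' @param smiles A single SMILES string.
#' @param lib A [load_library()] object.
#' @param mode `"count"` (default) or `"binary"`.
#' @param unique_matches Collapse automorphic matches (default `TRUE`).
#' @return Integer vector of length `length(lib)` named by pattern index.
#' @export
compute_fingerprint <- function(smiles, lib = load_library(),
                                mode = c("count", "binary"),
                                unique_matches = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(lib, "substructure_library"),
            is.character(smiles), length(smiles) == 1L)
  mol <- tryCatch(ChemmineOB::forEachMol("SMILES", smiles, identity),
                  error = function(e) NULL)
  if (is.null(mol)) stop_hs("unparsable structure: '%s'", smiles)
  counts <- vapply(lib$patterns, function(p) {
    as.integer(ChemmineOB::smartsSearch_OB(mol, p,
                                           uniqueMatches = unique_matches))
  }, integer(1), USE.NAMES = FALSE)
  if (mode == "binary") counts <- as.integer(counts > 0L)
  names(counts) <- seq_along(counts)
  counts
}

#' Fingerprint matrix for a set of molecules
#'
#' @param mols Molecule data.frame from [read_molecules()] (columns `id`,
#'   `smiles`) or a named character vector of SMILES.
#' @param lib,mode,unique_matches As in [compute_fingerprint()].
#' @return Integer matrix, one row per molecule (row names = ids), one
#'   column per library pattern.
#' @export
fingerprint_matrix <- function(mols, lib = load_library(),
                               mode = c("count", "binary"),
                               unique_matches = TRUE) {
  mode <- match.arg(mode)
  if (is.data.frame(mols)) {
    ids <- mols$id; smiles <- mols$smiles
  } else {
    smiles <- as.character(mols)
    ids <- names(mols) %||% as.character(seq_along(mols))
  }
  fp <- t(vapply(smiles, compute_fingerprint, integer(length(lib)),
                 lib = lib, mode = mode, unique_matches = unique_matches,
                 USE.NAMES = FALSE))
  rownames(fp) <- ids
  colnames(fp) <- paste0("p", seq_len(ncol(fp)))
  fp
}
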