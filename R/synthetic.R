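# Synthetic data generators.  Every generator is a pure function of its
# arguments (seed included) and returns a ground-truth manifest
# sufficient for downstream tests: descriptor matrices with planted
# filter targets, fingerprint count matrices with class-informative
# columns, toy docked complexes with planted interactions of known type
# and count, and a potency-annotated activity table.

#' Synthetic descriptor matrix with planted filter targets
#'
#' Two balanced classes; informative columns are unit-variance Gaussians
#' whose class means differ by `class_sep`; planted columns exercise the
#' preprocessing chain (sparse: >= 90% exact zeros; constant; duplicated:
#' exact copies of informative columns placed after their source).
#'
#' @param n Instances (>= 4).
#' @param p Total columns; must accommodate all planted ones.
#' @param n_informative Class-separated columns.
#' @param class_sep Mean shift between classes on informative columns.
#' @param n_sparse,n_constant,n_duplicated Planted removable columns.
#' @param seed Integer seed.
#' @return List with `matrix` (a labelled [descriptor_matrix()]) and
#'   `manifest` (names of informative / noise / sparse / constant /
#'   duplicated columns and the seed).
#' @export
gen_descriptor_matrix <- function(n = 100, p = 20, n_informative = 5,
                                  class_sep = 1.5, n_sparse = 3,
                                  n_constant = 2, n_duplicated = 2,
                                  seed = 1) {
  if (n < 4L) stop_hs("need n >= 4")
  n_planted <- n_informative + n_sparse + n_constant + n_duplicated
  if (n_planted > p) stop_hs("planted columns (%d) exceed p = %d", n_planted, p)
  if (n_duplicated > 0L && n_informative == 0L) {
    stop_hs("duplicated columns need informative sources")
  }
  n_noise <- p - n_planted
  with_seed(seed, {
    y <- sample(rep(c(0L, 1L), length.out = n))
    cols <- list(); nm <- character(0)
    for (k in seq_len(n_informative)) {
      cols[[length(cols) + 1L]] <- stats::rnorm(n) + class_sep * y
      nm <- c(nm, sprintf("inf%d", k))
    }
    for (k in seq_len(n_noise)) {
      cols[[length(cols) + 1L]] <- stats::rnorm(n)
      nm <- c(nm, sprintf("noise%d", k))
    }
    for (k in seq_len(n_sparse)) {
      v <- numeric(n)
      nz <- n - ceiling(0.9 * n)
      if (nz > 0L) v[sample.int(n, nz)] <- stats::rnorm(nz)
      cols[[length(cols) + 1L]] <- v
      nm <- c(nm, sprintf("sparse%d", k))
    }
    for (k in seq_len(n_constant)) {
      cols[[length(cols) + 1L]] <- rep(k, n)
      nm <- c(nm, sprintf("const%d", k))
    }
    for (k in seq_len(n_duplicated)) {
      src <- ((k - 1L) %% n_informative) + 1L
      cols[[length(cols) + 1L]] <- cols[[src]]
      nm <- c(nm, sprintf("dup%d_of_inf%d", k, src))
    }
    values <- do.call(cbind, cols)
    colnames(values) <- nm
    rownames(values) <- sprintf("mol%d", seq_len(n))
    manifest <- list(
      informative = nm[seq_len(n_informative)],
      noise = grep("^noise", nm, value = TRUE),
      sparse = grep("^sparse", nm, value = TRUE),
      constant = grep("^const", nm, value = TRUE),
      duplicated = grep("^dup", nm, value = TRUE),
      class_sep = class_sep, seed = seed)
    list(matrix = descriptor_matrix(values, labels = y), manifest = manifest)
  })
}

#' Synthetic substructure-count dataset
#'
#' Non-negative integer counts shaped like a substructure fingerprint
#' matrix (default width 4860): sparse Poisson background everywhere,
#' with `k_informative` randomly placed columns whose Poisson rate is
#' raised by `effect` in the positive class.  `effect = 0` produces a
#' label-free null dataset.
#'
#' @param n Instances (>= 20).
#' @param k_informative Number of class-informative columns.
#' @param effect Poisson-rate increment for the positive class.
#' @param width Fingerprint length.
#' @param seed Integer seed.
#' @return List with `x` (n x width integer matrix), `y` (0/1 labels)
#'   and `manifest` (informative column indices, rates, seed).
#' @export
gen_fingerprint_dataset <- function(n = 300, k_informative = 10, effect = 2,
                                    width = 4860, seed = 1) {
  if (n < 20L) stop_hs("need n >= 20")
  if (k_informative < 1L || k_informative > width) {
    stop_hs("need 1 <= k_informative <= width")
  }
  if (effect < 0) stop_hs("effect must be >= 0")
  base_rate <- 0.05; inf_rate <- 0.5
  with_seed(seed, {
    y <- sample(rep(c(0L, 1L), length.out = n))
    x <- matrix(stats::rpois(n * width, base_rate), n, width)
    info <- sort(sample.int(width, k_informative))
    for (j in info) {
      x[, j] <- stats::rpois(n, inf_rate + effect * y)
    }
    rownames(x) <- sprintf("mol%d", seq_len(n))
    colnames(x) <- paste0("p", seq_len(width))
    list(x = x, y = y,
         manifest = list(informative = info, base_rate = base_rate,
                         informative_rate = inf_rate, effect = effect,
                         seed = seed))
  })
}

# ---- toy complex construction ----------------------------------------------

pdb_line <- function(rec, serial, name, resid, chain, resno, xyz,
                     elem, charge = "") {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  paste0(sprintf("%-6s", rec), sprintf("%5d", serial), " ",
         name4, " ", sprintf("%-3s", resid), " ", chain,
         sprintf("%4d", resno), "    ",
         sprintf("%8.3f%8.3f%8.3f", xyz[1], xyz[2], xyz[3]),
         sprintf("%6.2f%6.2f", 1, 0), strrep(" ", 10),
         sprintf("%2s", elem), sprintf("%2s", charge))
}

hexagon <- function(center, radius = 1.39) {
  ang <- seq(0, 300, by = 60) * pi / 180
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
        center[3])
}

#' Synthetic docked complex with planted interactions
#'
#' Writes a syntactically valid single-model PDB whose protein residues
#' and LIG HETATM group are positioned so that the geometric profiler
#' fires exactly once per planted interaction and never otherwise.  Each
#' planted contact occupies its own residue slot 30 A from its
#' neighbours; decoy atoms sit far outside every cutoff.  Planted
#' geometries keep the largest feasible margin from all other rules'
#' cutoffs (at least 1 A; charged-pair contacts are additionally routed
#' to salt_bridge only, so no rule can double-fire).
#'
#' @param planted Named integer vector over
#'   `hbond, hydrophobic, salt_bridge, pi_stacking, pi_cation`, e.g.
#'   `c(salt_bridge = 3)`; may be empty for a contact-free complex.
#' @param decoys Number of far-away decoy protein residues.
#' @param seed Integer seed (used for decoy placement jitter).
#' @param path Optional file to write the PDB to.
#' @param id Complex id.
#' @return List with `pdb` (character vector of lines), `path` (or
#'   `NA`), `expected` (data.frame `type`, `count`) and `d_i`.
#' @export
gen_complex <- function(planted = c(salt_bridge = 1), decoys = 3, seed = 1,
                        path = NULL, id = "synthetic_complex") {
  types <- c("hbond", "hydrophobic", "salt_bridge", "pi_stacking", "pi_cation")
  planted <- planted[planted > 0]
  if (length(planted) && !all(names(planted) %in% types)) {
    stop_hs("unknown interaction type(s): %s",
            paste(setdiff(names(planted), types), collapse = ", "))
  }
  slots <- rep(names(planted), planted)
  lines <- character(0)
  serial <- 0L
  lig_atoms <- list()   # deferred so HETATM records follow all ATOM records
  counters <- new.env()
  lig_name <- function(elem) {
    k <- (get0(elem, envir = counters, inherits = FALSE) %||% 0L) + 1L
    assign(elem, k, counters)
    paste0(elem, k)
  }
  emit <- function(name, resid, resno, xyz, elem) {
    serial <<- serial + 1L
    lines <<- c(lines, pdb_line("ATOM", serial, name, resid, "A", resno,
                                xyz, elem))
  }
  defer_lig <- function(xyz, elem, charge = "") {
    lig_atoms[[length(lig_atoms) + 1L]] <<-
      list(name = lig_name(elem), xyz = xyz, elem = elem, charge = charge)
  }
  for (k in seq_along(slots)) {
    c0 <- c(30 * (k - 1), 0, 0)
    switch(slots[k],
      salt_bridge = {
        emit("CB", "ASP", k, c0 + c(0, -2.8, 0), "C")
        emit("CG", "ASP", k, c0 + c(0, -1.5, 0), "C")
        emit("OD1", "ASP", k, c0 + c(-1.1, -0.7, 0), "O")
        emit("OD2", "ASP", k, c0 + c(1.1, -0.7, 0), "O")
        defer_lig(c0 + c(0, 4.1, 0), "N", "1+")   # centroid distance 4.8 A
      },
      hbond = {
        emit("CB", "SER", k, c0 + c(0, -1.5, 0), "C")
        emit("OG", "SER", k, c0, "O")
        defer_lig(c0 + c(0, 3.0, 0), "O")
      },
      hydrophobic = {
        emit("CB", "ALA", k, c0, "C")
        defer_lig(c0 + c(0, 3.6, 0), "C")
      },
      pi_stacking = {
        ring <- hexagon(c0)
        nms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
        for (i in 1:6) emit(nms[i], "PHE", k, ring[i, ], "C")
        lig_ring <- hexagon(c0 + c(0, 0, 3.8))
        for (i in 1:6) defer_lig(lig_ring[i, ], "C")
      },
      pi_cation = {
        ring <- hexagon(c0)
        nms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
        for (i in 1:6) emit(nms[i], "PHE", k, ring[i, ], "C")
        defer_lig(c0 + c(0, 0, 4.5), "N", "1+")
      })
  }
  with_seed(seed, {
    for (d in seq_len(decoys)) {
      jit <- stats::runif(3, -0.5, 0.5)
      emit("CA", "GLY", 800 + d, c(30 * (d - 1), -40, 0) + jit, "C")
    }
  })
  if (length(lig_atoms) == 0L) {
    # a lone, far-away noble-gas-like ligand atom keeps the file valid
    lig_atoms <- list(list(name = "C1", xyz = c(0, 60, 0), elem = "C",
                           charge = ""))
  }
  for (a in lig_atoms) {
    serial <- serial + 1L
    lines <- c(lines, pdb_line("HETATM", serial, a$name, "LIG", "L", 900,
                               a$xyz, a$elem, a$charge))
  }
  lines <- c(lines, "END")
  expected <- data.frame(type = names(planted),
                         count = as.integer(planted),
                         stringsAsFactors = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  list(pdb = lines, path = path %||% NA_character_, expected = expected,
       d_i = sum(planted))
}

#' Synthetic potency-annotated activity table
#'
#' A stand-in for a curated inhibitor table: unique ids, simple valid
#' SMILES, and IC50 values (µM) drawn log-uniformly strictly below the
#' cutoff for the actives and strictly above it for the inactives, so
#' potency labelling at `cutoff` recovers the requested composition by
#' construction.
#'
#' @param n_active,n_inactive Class sizes.
#' @param cutoff Potency cutoff in µM.
#' @param seed Integer seed.
#' @return data.frame with columns `id`, `smiles`, `ic50_um` in shuffled
#'   order.
#' @export
gen_activity_table <- function(n_active = 81, n_inactive = 94,
                               cutoff = 0.05, seed = 1) {
  n <- n_active + n_inactive
  prefixes <- c("", "CC(C)", "OC")
  groups <- c("", "O", "N", "C(=O)O", "c1ccccc1")
  smiles <- character(n)
  for (i in seq_len(n)) {
    k <- 1L + ((i - 1L) %% 12L)
    g <- groups[1L + (((i - 1L) %/% 12L) %% 5L)]
    p <- prefixes[1L + (((i - 1L) %/% 60L) %% 3L)]
    smiles[i] <- paste0(p, strrep("C", k), g)
  }
  if (anyDuplicated(smiles[seq_len(min(n, 180L))])) {
    stop_hs("internal: SMILES pool collision")   # n > 180 reuses the pool
  }
  with_seed(seed, {
    ic50 <- c(10^stats::runif(n_active, -4, log10(cutoff * 0.98)),
              10^stats::runif(n_inactive, log10(cutoff * 1.02), 2))
    ord <- sample.int(n)
    data.frame(id = sprintf("SYN%04d", seq_len(n)),
               smiles = smiles[ord],
               ic50_um = ic50[ord],
               stringsAsFactors = FALSE)
  })
}

#' Synthetic two-space screening study
#'
#' Builds a complete paired dataset for the end-to-end pipeline: shared
#' balanced labels; descriptors with class signal (chemical space);
#' substructure counts with class signal (protein space); and planted
#' interaction counts, inside the window for every active and outside it
#' for every inactive.  Split into a training and an evaluation portion.
#'
#' @param n_train,n_eval Instances per portion.
#' @param class_sep,effect Descriptor shift / fingerprint rate increment.
#' @param fp_width Fingerprint length.
#' @param window A [threshold_window()].
#' @param seed Integer seed.
#' @return List with `train` and `eval` (each: `descriptors` a labelled
#'   [descriptor_matrix()], `fp` count matrix, `y` named labels, `d_i`
#'   named counts) and `manifest`.
#' @export
gen_screening_study <- function(n_train = 200, n_eval = 100, class_sep = 2,
                                effect = 2, fp_width = 4860,
                                window = threshold_window(9, 12),
                                seed = 1) {
  n <- n_train + n_eval
  desc <- gen_descriptor_matrix(n = n, p = 24, n_informative = 6,
                                class_sep = class_sep, n_sparse = 3,
                                n_constant = 2, n_duplicated = 2,
                                seed = child_seed(seed, 21L))
  y <- desc$matrix$labels
  fp <- gen_fingerprint_dataset_for_labels(y, k_informative = 10,
                                           effect = effect, width = fp_width,
                                           seed = child_seed(seed, 22L))
  ids <- rownames(desc$matrix$values)
  rownames(fp) <- ids
  out_pool <- setdiff(0:(window$d_max + 5L),
                      (window$d_min - 1L):(window$d_max + 1L))
  if (!length(out_pool)) stop_hs("window leaves no out-of-window counts")
  d_i <- with_seed(child_seed(seed, 23L), {
    ifelse(y == 1L,
           sample(window$d_min:window$d_max, n, replace = TRUE),
           sample(out_pool, n, replace = TRUE))
  })
  names(d_i) <- ids
  names(y) <- ids
  tr <- seq_len(n_train); ev <- n_train + seq_len(n_eval)
  portion <- function(idx) {
    list(descriptors = descriptor_matrix(desc$matrix$values[idx, , drop = FALSE],
                                         labels = y[idx]),
         fp = fp[idx, , drop = FALSE],
         y = y[idx],
         d_i = d_i[idx])
  }
  list(train = portion(tr), eval = portion(ev),
       manifest = c(desc$manifest,
                    list(window = c(window$d_min, window$d_max), seed = seed)))
}

# fingerprint counts conditioned on externally supplied labels
gen_fingerprint_dataset_for_labels <- function(y, k_informative = 10,
                                               effect = 2, width = 4860,
                                               seed = 1) {
  n <- length(y)
  with_seed(seed, {
    x <- matrix(stats::rpois(n * width, 0.05), n, width)
    info <- sort(sample.int(width, k_informative))
    for (j in info) x[, j] <- stats::rpois(n, 0.5 + effect * y)
    colnames(x) <- paste0("p", seq_len(width))
    attr(x, "informative") <- info
    x
  })
}
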