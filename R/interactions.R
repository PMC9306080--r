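# Geometric protein-ligand interaction profiling for docked complexes.
# The profiler types contacts with simplified geometric criteria whose
# default cutoffs mirror the published PLIP conventions; alternatively a
# real PLIP report can be ingested (ingest_plip_report) and counted with
# the same semantics.

#' Geometric rule set for interaction detection
#'
#' Distance cutoffs in Angstrom, angles in degrees.  Defaults follow the
#' published conventions of protein-ligand interaction profiling:
#' hydrogen-bond donor-acceptor heavy-atom distance <= 4.1 A (donor angle
#' >= 100 deg when an explicit hydrogen is present), apolar carbon-carbon
#' contacts <= 4.0 A, charged-group centroid distance <= 5.5 A for salt
#' bridges, ring-centroid distance <= 5.5 A with interplanar angle
#' <= 30 deg (parallel) or >= 60 deg (T-shaped) for pi-stacking, and
#' ring-centroid to cation distance <= 6.0 A for pi-cation contacts.
#' `bond_max` is the heavy-atom distance used to infer ligand
#' connectivity.
#'
#' @param hbond_dist,hbond_angle,hydrophobic_dist,saltbridge_dist
#'   Cutoffs for the respective interaction types.
#' @param pistack_dist,pistack_parallel,pistack_tshape,pication_dist
#'   Ring-geometry cutoffs.
#' @param bond_max,ring_planarity Ligand bond-perception distance and
#'   maximum RMS out-of-plane deviation for an aromatic ring.
#' @return A list of class `"interaction_rules"`.
#' @export
interaction_rules <- function(hbond_dist = 4.1, hbond_angle = 100,
                              hydrophobic_dist = 4.0, saltbridge_dist = 5.5,
                              pistack_dist = 5.5, pistack_parallel = 30,
                              pistack_tshape = 60, pication_dist = 6.0,
                              bond_max = 1.9, ring_planarity = 0.2) {
  structure(as.list(environment()), class = "interaction_rules")
}

parse_pdb_charge <- function(ch) {
  ch <- trimws(as.character(ch))
  out <- integer(length(ch))
  has <- !is.na(ch) & nzchar(ch)
  v <- ch[has]
  # PDB writes "1+", "2-"; tolerate "+1"/"-1" too
  sign <- ifelse(grepl("-", v), -1L, ifelse(grepl("\\+", v), 1L, 1L))
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", v)))
  num[is.na(num)] <- 0L
  out[has] <- sign * num
  out
}

#' Parse a docked protein-ligand complex from PDB
#'
#' Protein atoms come from ATOM records, the ligand from a HETATM group
#' selected by residue name (waters are never eligible).  When several
#' distinct non-water HETATM groups are present a selector is required.
#' Only the first MODEL of a multi-model file is read and only the first
#' alternate location of each atom is kept.
#'
#' @param path PDB file.
#' @param ligand Optional ligand residue name (e.g. `"LIG"`).
#' @param id Complex identifier (defaults to the file name).
#' @return An object of class `"complex_structure"`: list with `id`,
#'   `protein` and `ligand` atom data.frames (columns `name`, `elem`,
#'   `resid`, `chain`, `resno`, `x`, `y`, `z`, `charge`).
#' @export
parse_complex <- function(path, ligand = NULL,
                          id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop_hs("file not found: %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  # resolve insertion codes: first record wins per (chain, resno, name)
  key <- paste(at$chain, at$resno, at$elety, at$type, sep = "|")
  at <- at[!duplicated(key), , drop = FALSE]
  elem <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                 trimws(at$elesy), NA_character_)
  miss <- is.na(elem)
  if (any(miss)) elem[miss] <- bio3d::atom2ele(at$elety[miss])
  df <- data.frame(name = at$elety, elem = toupper(elem), resid = at$resid,
                   chain = ifelse(is.na(at$chain), "", at$chain),
                   resno = at$resno, x = at$x, y = at$y, z = at$z,
                   charge = parse_pdb_charge(at$charge),
                   type = at$type, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop_hs("non-finite coordinates in %s", path)
  }
  protein <- df[df$type == "ATOM", , drop = FALSE]
  het <- df[df$type == "HETATM" & !df$resid %in% c("HOH", "WAT", "DOD"), ,
            drop = FALSE]
  if (nrow(het) == 0L) stop_hs("no ligand: no non-water HETATM group in %s", path)
  groups <- unique(het[, c("resid", "chain", "resno")])
  if (!is.null(ligand)) groups <- groups[groups$resid == ligand, , drop = FALSE]
  if (nrow(groups) == 0L) {
    stop_hs("no HETATM group matches ligand selector '%s'", ligand)
  }
  if (nrow(groups) > 1L) {
    stop_hs("multiple candidate ligand groups (%s): disambiguate with `ligand`",
            paste(sprintf("%s/%s/%d", groups$resid, groups$chain, groups$resno),
                  collapse = ", "))
  }
  lig <- het[het$resid == groups$resid & het$chain == groups$chain &
               het$resno == groups$resno, , drop = FALSE]
  structure(list(id = id,
                 protein = protein[, setdiff(names(protein), "type")],
                 ligand = lig[, setdiff(names(lig), "type")]),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("complex_structure '%s': %d protein atoms, %d ligand atoms (%s)\n",
              x$id, nrow(x$protein), nrow(x$ligand),
              x$ligand$resid[1]))
  invisible(x)
}

#' Apply a rigid-body transform to a complex
#'
#' Rotates (3x3 matrix `R`) and translates (length-3 `t`) protein and
#' ligand jointly; interaction profiles are invariant under this.
#'
#' @param cx A [parse_complex()] structure.
#' @param R Rotation matrix.
#' @param t Translation vector.
#' @return The transformed `complex_structure`.
#' @export
transform_complex <- function(cx, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(inherits(cx, "complex_structure"))
  mv <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + t[1]; df$y <- xyz[, 2] + t[2]; df$z <- xyz[, 3] + t[3]
    df
  }
  cx$protein <- mv(cx$protein); cx$ligand <- mv(cx$ligand)
  cx
}

# ---- residue templates ------------------------------------------------------

# hydrogen-bond capable protein heavy atoms (implicit-hydrogen templates)
PROT_DONORS <- list(
  ".ALL" = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), TRP = "NE1",
  ASN = "ND2", GLN = "NE2")
PROT_ACCEPTORS <- list(
  ".ALL" = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), SER = "OG", THR = "OG1",
  TYR = "OH", ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"), MET = "SD")
PROT_ANION_GROUPS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
PROT_CATION_GROUPS <- list(LYS = "NZ", ARG = c("CZ", "NH1", "NH2"),
                           HIS = c("ND1", "NE2"))
# side-chain carbons not bonded to N or O
PROT_APOLAR <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  PRO = c("CB", "CG"), LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  THR = "CG2", HIS = "CB", GLU = c("CB", "CG"), ASP = "CB",
  GLN = c("CB", "CG"), ASN = "CB")
PROT_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

template_atoms <- function(protein, templates) {
  hit <- rep(FALSE, nrow(protein))
  all_names <- templates[[".ALL"]]
  if (!is.null(all_names)) hit <- hit | protein$name %in% all_names
  for (res in setdiff(names(templates), ".ALL")) {
    hit <- hit | (protein$resid == res & protein$name %in% templates[[res]])
  }
  which(hit)
}

res_key <- function(df, i) {
  sprintf("%s%d%s", df$resid[i], df$resno[i], df$chain[i])
}

pair_dists <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m Euclidean distances
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (k in 1:3) out <- out + outer(a[, k], b[, k], "-")^2
  sqrt(out)
}

coords <- function(df, idx = seq_len(nrow(df))) {
  as.matrix(df[idx, c("x", "y", "z"), drop = FALSE])
}

# least-squares ring plane: returns centroid, unit normal, rms deviation
ring_plane <- function(xyz) {
  c0 <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, c0))
  normal <- s$v[, 3]
  rms <- sqrt(mean((sweep(xyz, 2, c0) %*% normal)^2))
  list(centroid = c0, normal = normal, rms = rms)
}

# ligand connectivity inferred from heavy-atom distances
ligand_bonds <- function(lig, bond_max) {
  n <- nrow(lig)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  d <- pair_dists(coords(lig), coords(lig))
  lim <- matrix(bond_max, n, n)
  isH <- lig$elem == "H"
  lim[isH, ] <- 1.3; lim[, isH] <- 1.3
  idx <- which(d > 0.4 & d <= lim & upper.tri(d), arr.ind = TRUE)
  idx
}

ligand_rings <- function(lig, bonds, planarity) {
  heavy <- which(lig$elem %in% c("C", "N"))
  if (length(heavy) < 5L) return(list())
  keep <- bonds[bonds[, 1] %in% heavy & bonds[, 2] %in% heavy, , drop = FALSE]
  if (nrow(keep) == 0L) return(list())
  g <- igraph::graph_from_edgelist(matrix(as.character(keep), ncol = 2),
                                   directed = FALSE)
  rings <- list()
  for (size in c(5L, 6L)) {
    if (igraph::vcount(g) < size) next
    iso <- igraph::subgraph_isomorphisms(igraph::make_ring(size), g)
    sets <- unique(lapply(iso, function(m) {
      sort(as.integer(igraph::V(g)$name[as.integer(m)]))
    }))
    for (s in sets) {
      pl <- ring_plane(coords(lig, s))
      if (pl$rms <= planarity) rings[[length(rings) + 1L]] <- s
    }
  }
  unique(rings)
}

#' Detect typed protein-ligand contacts
#'
#' Applies the geometric rules to a parsed complex and returns one record
#' per (type, residue, ligand atom-or-ring) triple.  Hydrogen-bond
#' detection uses implicit-hydrogen heavy-atom templates when the
#' structure carries no hydrogens; contacts between oppositely charged
#' groups are typed as salt bridges only, and apolar contacts between the
#' two rings of a detected pi-stack are suppressed so one physical
#' contact yields one record.
#'
#' @param cx A [parse_complex()] structure.
#' @param rules An [interaction_rules()] set.
#' @return data.frame with columns `type`, `residue`, `ligand_atom`,
#'   `distance` (A).  Zero rows when no contact satisfies any rule.
#' @export
detect_interactions <- function(cx, rules = interaction_rules()) {
  stopifnot(inherits(cx, "complex_structure"),
            inherits(rules, "interaction_rules"))
  prot <- cx$protein
  lig <- cx$ligand
  rec <- list()
  add <- function(type, residue, ligand_atom, distance) {
    rec[[length(rec) + 1L]] <<- data.frame(
      type = type, residue = residue, ligand_atom = ligand_atom,
      distance = round(distance, 3), stringsAsFactors = FALSE)
  }
  if (nrow(prot) == 0L || nrow(lig) == 0L) {
    return(data.frame(type = character(0), residue = character(0),
                      ligand_atom = character(0), distance = numeric(0)))
  }

  bonds <- ligand_bonds(lig, rules$bond_max)
  bonded_to <- function(i) {
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
  }
  lig_has_H <- any(lig$elem == "H")
  lig_heavy <- which(lig$elem != "H")

  # ligand functional roles
  lig_cations <- which(lig$charge > 0L)
  lig_anions <- which(lig$charge < 0L)
  lig_polar <- which(lig$elem %in% c("N", "O"))
  lig_donors <- if (lig_has_H) {
    Filter(function(i) any(lig$elem[bonded_to(i)] == "H"), lig_polar)
  } else setdiff(lig_polar, lig_anions)
  lig_acceptors <- setdiff(lig_polar, lig_cations)
  lig_apolar <- Filter(function(i) {
    !any(lig$elem[bonded_to(i)] %in% c("N", "O"))
  }, which(lig$elem == "C"))
  rings_l <- ligand_rings(lig, bonds, rules$ring_planarity)

  # protein groups
  don_p <- template_atoms(prot, PROT_DONORS)
  acc_p <- template_atoms(prot, PROT_ACCEPTORS)
  apolar_p <- template_atoms(prot, PROT_APOLAR)
  charged_groups <- function(templates, sign) {
    out <- list()
    for (res in names(templates)) {
      rows <- which(prot$resid == res & prot$name %in% templates[[res]])
      for (key in unique(vapply(rows, function(i) res_key(prot, i), "")))  {
        sel <- rows[vapply(rows, function(i) res_key(prot, i), "") == key]
        out[[length(out) + 1L]] <- list(key = key, atoms = sel, sign = sign,
                                        centroid = colMeans(coords(prot, sel)))
      }
    }
    out
  }
  anion_g <- charged_groups(PROT_ANION_GROUPS, -1L)
  cation_g <- charged_groups(PROT_CATION_GROUPS, +1L)
  rings_p <- list()
  for (res in names(PROT_RINGS)) {
    rows <- which(prot$resid == res & prot$name %in% PROT_RINGS[[res]])
    for (key in unique(vapply(rows, function(i) res_key(prot, i), ""))) {
      sel <- rows[vapply(rows, function(i) res_key(prot, i), "") == key]
      if (length(sel) >= 5L) {
        rings_p[[length(rings_p) + 1L]] <- list(key = key, atoms = sel)
      }
    }
  }

  # --- pi-stacking (first: its rings suppress hydrophobic duplicates) ---
  stacked_pairs <- list()
  for (rp in rings_p) {
    pp <- ring_plane(coords(prot, rp$atoms))
    for (ri in seq_along(rings_l)) {
      pl <- ring_plane(coords(lig, rings_l[[ri]]))
      d <- sqrt(sum((pp$centroid - pl$centroid)^2))
      if (d > rules$pistack_dist) next
      ang <- acos(pmin(1, abs(sum(pp$normal * pl$normal)))) * 180 / pi
      if (ang <= rules$pistack_parallel || ang >= rules$pistack_tshape) {
        add("pi_stacking", rp$key, paste0("ring", ri), d)
        stacked_pairs[[length(stacked_pairs) + 1L]] <-
          list(p = rp$atoms, l = rings_l[[ri]])
      }
    }
  }

  # --- salt bridges (charged-group centroids) ---
  salt_atom_pairs <- matrix(integer(0), ncol = 2)
  for (g in c(anion_g, cation_g)) {
    partners <- if (g$sign < 0L) lig_cations else lig_anions
    for (i in partners) {
      d <- sqrt(sum((g$centroid - unlist(coords(lig, i)))^2))
      if (d <= rules$saltbridge_dist) {
        add("salt_bridge", g$key, lig$name[i], d)
      }
      # any charged-pair contact is never additionally a hydrogen bond
      salt_atom_pairs <- rbind(salt_atom_pairs,
                               cbind(g$atoms, rep(i, length(g$atoms))))
    }
  }

  # --- pi-cation ---
  for (rp in rings_p) {
    pp <- ring_plane(coords(prot, rp$atoms))
    for (i in lig_cations) {
      d <- sqrt(sum((pp$centroid - unlist(coords(lig, i)))^2))
      if (d <= rules$pication_dist) add("pi_cation", rp$key, lig$name[i], d)
    }
  }
  for (g in cation_g) {
    for (ri in seq_along(rings_l)) {
      pl <- ring_plane(coords(lig, rings_l[[ri]]))
      d <- sqrt(sum((g$centroid - pl$centroid)^2))
      if (d <= rules$pication_dist) add("pi_cation", g$key, paste0("ring", ri), d)
    }
  }

  # --- hydrogen bonds (heavy-atom distance, donor angle when H known) ---
  hb_pair_ok <- function(p_i, l_i) {
    !any(salt_atom_pairs[, 1] == p_i & salt_atom_pairs[, 2] == l_i)
  }
  hb <- list()
  consider <- rbind(
    if (length(don_p) && length(lig_acceptors))
      expand.grid(p = don_p, l = lig_acceptors, pd = TRUE),
    if (length(acc_p) && length(lig_donors))
      expand.grid(p = acc_p, l = unlist(lig_donors), pd = FALSE))
  if (!is.null(consider) && nrow(consider)) {
    for (r in seq_len(nrow(consider))) {
      p_i <- consider$p[r]; l_i <- consider$l[r]
      if (!hb_pair_ok(p_i, l_i)) next
      d <- sqrt(sum((unlist(coords(prot, p_i)) - unlist(coords(lig, l_i)))^2))
      if (d > rules$hbond_dist) next
      if (!consider$pd[r] && lig_has_H) {
        hs <- bonded_to(l_i); hs <- hs[lig$elem[hs] == "H"]
        ang <- vapply(hs, function(h) {
          v1 <- unlist(coords(lig, l_i)) - unlist(coords(lig, h))
          v2 <- unlist(coords(prot, p_i)) - unlist(coords(lig, h))
          acos(pmin(1, pmax(-1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        }, numeric(1))
        if (length(ang) && max(ang) < rules$hbond_angle) next
      }
      key <- paste(res_key(prot, p_i), lig$name[l_i])
      if (is.null(hb[[key]]) || d < hb[[key]]$d) {
        hb[[key]] <- list(res = res_key(prot, p_i), at = lig$name[l_i], d = d)
      }
    }
    for (h in hb) add("hbond", h$res, h$at, h$d)
  }

  # --- hydrophobic contacts (residue x ligand-atom, minimum distance) ---
  if (length(apolar_p) && length(lig_apolar)) {
    la <- unlist(lig_apolar)
    dm <- pair_dists(coords(prot, apolar_p), coords(lig, la))
    in_stack <- function(p_i, l_i) {
      any(vapply(stacked_pairs, function(sp) {
        p_i %in% sp$p && l_i %in% sp$l
      }, logical(1)))
    }
    hy <- list()
    hits <- which(dm <= rules$hydrophobic_dist, arr.ind = TRUE)
    if (nrow(hits)) {
      for (r in seq_len(nrow(hits))) {
        p_i <- apolar_p[hits[r, 1]]; l_i <- la[hits[r, 2]]
        if (length(stacked_pairs) && in_stack(p_i, l_i)) next
        key <- paste(res_key(prot, p_i), lig$name[l_i])
        d <- dm[hits[r, 1], hits[r, 2]]
        if (is.null(hy[[key]]) || d < hy[[key]]$d) {
          hy[[key]] <- list(res = res_key(prot, p_i), at = lig$name[l_i], d = d)
        }
      }
      for (h in hy) add("hydrophobic", h$res, h$at, h$d)
    }
  }

  if (length(rec) == 0L) {
    return(data.frame(type = character(0), residue = character(0),
                      ligand_atom = character(0), distance = numeric(0)))
  }
  out <- do.call(rbind, rec)
  out[order(out$type, out$residue, out$ligand_atom), , drop = FALSE]
}

#' Interaction profile of a complex
#'
#' Wraps [detect_interactions()] and attaches the total interaction
#' count `d_i` (the number of typed contact records), the quantity fused
#' with the protein-space classifier output during hit optimization.
#'
#' @param cx A [parse_complex()] structure.
#' @param rules An [interaction_rules()] set.
#' @return Object of class `"interaction_profile"`: list with `id`,
#'   `records` and `d_i`.
#' @export
interaction_profile <- function(cx, rules = interaction_rules()) {
  records <- detect_interactions(cx, rules)
  structure(list(id = cx$id, records = records, d_i = nrow(records)),
            class = "interaction_profile")
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat(sprintf("interaction_profile '%s': d_i = %d\n", x$id, x$d_i))
  if (x$d_i > 0) {
    tab <- table(x$records$type)
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ingest an external PLIP report
#'
#' Reads a PLIP XML report (or the plain-text report with markdown-style
#' interaction tables) for a single complex and maps its categories onto
#' the profiler's types.  Water bridges, halogen bonds and metal
#' complexes are counted under `"other"` and included in `d_i` by
#' default.
#'
#' @param path Report file (`.xml` or text).
#' @param include_other Count unmapped categories in `d_i`?
#' @return An `"interaction_profile"`.
#' @export
ingest_plip_report <- function(path, include_other = TRUE) {
  if (!file.exists(path)) stop_hs("file not found: %s", path)
  head_ <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "\n")
  if (grepl("<", head_, fixed = TRUE)) {
    prof <- plip_xml_records(path)
  } else if (grepl("Prediction of noncovalent interactions|\\*\\*", head_)) {
    prof <- plip_txt_records(path)
  } else {
    stop_hs("unrecognized report schema: %s", path)
  }
  if (!include_other) prof <- prof[prof$type != "other", , drop = FALSE]
  structure(list(id = tools::file_path_sans_ext(basename(path)),
                 records = prof, d_i = nrow(prof)),
            class = "interaction_profile")
}

PLIP_TYPE_MAP <- c(
  hydrophobic_interaction = "hydrophobic", hydrogen_bond = "hbond",
  salt_bridge = "salt_bridge", pi_stack = "pi_stacking",
  pi_cation_interaction = "pi_cation", water_bridge = "other",
  halogen_bond = "other", metal_complex = "other")

plip_xml_records <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_hs("unrecognized report schema: %s", path))
  recs <- list()
  for (node_name in names(PLIP_TYPE_MAP)) {
    nodes <- xml2::xml_find_all(doc, sprintf(".//%s", node_name))
    for (nd in nodes) {
      restype <- xml2::xml_text(xml2::xml_find_first(nd, "./restype"))
      resnr <- xml2::xml_text(xml2::xml_find_first(nd, "./resnr"))
      chain <- xml2::xml_text(xml2::xml_find_first(nd, "./reschain"))
      recs[[length(recs) + 1L]] <- data.frame(
        type = unname(PLIP_TYPE_MAP[node_name]),
        residue = paste0(restype %||% "", resnr %||% "", chain %||% ""),
        ligand_atom = NA_character_, distance = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) {
    if (length(xml2::xml_find_all(doc, ".//bindingsite | .//report")) == 0L) {
      stop_hs("unrecognized report schema: %s", path)
    }
    return(data.frame(type = character(0), residue = character(0),
                      ligand_atom = character(0), distance = numeric(0)))
  }
  do.call(rbind, recs)
}

PLIP_TXT_SECTIONS <- c(
  "Hydrophobic Interactions" = "hydrophobic", "Hydrogen Bonds" = "hbond",
  "Salt Bridges" = "salt_bridge", "pi-Stacking" = "pi_stacking",
  "pi-Cation Interactions" = "pi_cation", "Water Bridges" = "other",
  "Halogen Bonds" = "other", "Metal Complexes" = "other")

plip_txt_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  current <- NA_character_
  for (ln in lines) {
    sec <- gsub("\\*", "", trimws(ln))
    if (sec %in% names(PLIP_TXT_SECTIONS)) {
      current <- PLIP_TXT_SECTIONS[[sec]]
      next
    }
    if (!is.na(current) && startsWith(trimws(ln), "|")) {
      body <- trimws(ln)
      if (grepl("RESNR", body) || grepl("^[-=+| ]+$", body)) next  # header / rule
      recs[[length(recs) + 1L]] <- data.frame(
        type = current, residue = NA_character_,
        ligand_atom = NA_character_, distance = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(type = character(0), residue = character(0),
                      ligand_atom = character(0), distance = numeric(0)))
  }
  do.call(rbind, recs)
}

#' Profile a directory or set of complexes
#'
#' Convenience wrapper: parses and profiles several PDB files and
#' returns a flat table of per-complex interaction counts.
#'
#' @param paths PDB file paths (ids default to file names).
#' @param ligand,rules Passed to [parse_complex()] /
#'   [interaction_profile()].
#' @return data.frame with columns `id` and `d_i`; the full profiles are
#'   attached as `attr(, "profiles")`.
#' @export
profile_complexes <- function(paths, ligand = NULL,
                              rules = interaction_rules()) {
  profs <- lapply(paths, function(p) {
    interaction_profile(parse_complex(p, ligand = ligand), rules)
  })
  out <- data.frame(id = vapply(profs, `[[`, "", "id"),
                    d_i = vapply(profs, `[[`, 0L, "d_i"),
                    stringsAsFactors = FALSE)
  attr(out, "profiles") <- profs
  out
}
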