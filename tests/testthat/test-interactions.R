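test_that("PDB parsing separates protein and ligand, resolves altlocs", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N  ",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  1.00  0.00           C  ",
    "ATOM      3  CA BALA A   1      11.700   6.100  -5.200  1.00  0.00           C  ",
    "ATOM      4  C   ALA A   1      12.800   7.000  -5.000  1.00  0.00           C  ",
    "ATOM      5  O   ALA A   1      13.500   6.500  -4.200  1.00  0.00           O  ",
    "HETATM    6  N1  LIG L 900       2.000   0.000   0.000  1.00  0.00           N1+",
    "HETATM    7  C1  LIG L 900       3.400   0.000   0.000  1.00  0.00           C  ",
    "HETATM    8  C2  LIG L 900       4.800   0.000   0.000  1.00  0.00           C  ",
    "HETATM    9  O   HOH W 901       8.000   0.000   0.000  1.00  0.00           O  ",
    "END"), tf)
  cx <- parse_complex(tf)
  expect_equal(nrow(cx$protein), 4L)       # altloc B dropped
  expect_equal(nrow(cx$ligand), 3L)        # waters never selectable
  expect_equal(cx$ligand$charge, c(1L, 0L, 0L))

  # a water-only HETATM section has no ligand
  tf2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N  ",
    "HETATM    2  O   HOH W 901       8.000   0.000   0.000  1.00  0.00           O  ",
    "END"), tf2)
  expect_error(parse_complex(tf2), "no ligand")

  # two candidate groups require a selector
  tf3 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N  ",
    "HETATM    2  C1  LIG L 900       2.000   0.000   0.000  1.00  0.00           C  ",
    "HETATM    3  C1  XYZ M 901       9.000   0.000   0.000  1.00  0.00           C  ",
    "END"), tf3)
  expect_error(parse_complex(tf3), "multiple candidate")
  expect_equal(nrow(parse_complex(tf3, ligand = "LIG")$ligand), 1L)
})

test_that("planted interactions are recovered exactly, type by type", {
  cases <- list(c(hbond = 1), c(hydrophobic = 1), c(salt_bridge = 1),
                c(pi_stacking = 1), c(pi_cation = 1),
                c(salt_bridge = 3),
                c(hbond = 1, hydrophobic = 1, salt_bridge = 1),
                c(hbond = 2, pi_stacking = 1, pi_cation = 1))
  for (pl in cases) {
    cf <- complex_from_gen(pl, seed = 2)
    prof <- interaction_profile(cf$cx)
    expect_equal(prof$d_i, sum(pl), info = paste(names(pl), collapse = "+"))
    got <- table(prof$records$type)
    for (ty in names(pl)) {
      expect_equal(unname(got[ty]), unname(pl[ty]), ignore_attr = TRUE,
                   info = ty)
    }
  }
  # empty plant: d_i = 0
  cf0 <- complex_from_gen(integer(0), seed = 2)
  expect_equal(interaction_profile(cf0$cx)$d_i, 0L)
})

test_that("contacts beyond their cutoff are not reported", {
  # donor/acceptor pair at 4.5 A: outside the 4.1 A hydrogen-bond cutoff
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CB  SER A   1       0.000  -1.500   0.000  1.00  0.00           C  ",
    "ATOM      2  OG  SER A   1       0.000   0.000   0.000  1.00  0.00           O  ",
    "HETATM    3  O1  LIG L 900       0.000   4.500   0.000  1.00  0.00           O  ",
    "END"), tf)
  expect_equal(interaction_profile(parse_complex(tf))$d_i, 0L)
})

test_that("d_i is invariant under rigid-body motion and rule-monotone", {
  cf <- complex_from_gen(c(hbond = 1, salt_bridge = 2, pi_stacking = 1),
                         seed = 6)
  d0 <- interaction_profile(cf$cx)$d_i
  for (s in c(3, 9)) {
    cx2 <- transform_complex(cf$cx, random_rotation(s),
                             t = c(7.5, -12.2, 3.3) * s)
    expect_equal(interaction_profile(cx2)$d_i, d0)
  }
  # tightening every distance cutoff can never increase d_i
  tight <- interaction_rules(hbond_dist = 3.0, hydrophobic_dist = 3.0,
                             saltbridge_dist = 4.0, pistack_dist = 4.0,
                             pication_dist = 4.0)
  expect_lte(interaction_profile(cf$cx, tight)$d_i, d0)
  # removing a ligand atom never increases contacts
  cx3 <- cf$cx
  cx3$ligand <- cx3$ligand[-1, , drop = FALSE]
  expect_lte(interaction_profile(cx3)$d_i, d0)
})

test_that("PLIP reports are ingested and categories mapped", {
  counts <- c(hydrogen_bond = 4, hydrophobic_interaction = 3,
              salt_bridge = 1, water_bridge = 1)
  tf <- tempfile(fileext = ".xml")
  writeLines(synthetic_plip_xml(counts), tf)
  prof <- ingest_plip_report(tf)
  expect_equal(prof$d_i, 9L)
  expect_equal(sum(prof$records$type == "hbond"), 4L)
  expect_equal(sum(prof$records$type == "other"), 1L)
  expect_equal(ingest_plip_report(tf, include_other = FALSE)$d_i, 8L)

  # empty report
  tf0 <- tempfile(fileext = ".xml")
  writeLines("<report><bindingsite><interactions/></bindingsite></report>", tf0)
  expect_equal(ingest_plip_report(tf0)$d_i, 0L)

  # garbage is rejected
  tfg <- tempfile()
  writeLines("not a report", tfg)
  expect_error(ingest_plip_report(tfg), "schema")

  # the packaged profiler and a PLIP-style report agree on a planted
  # salt-bridge fixture when the report mirrors the true contact count
  cf <- complex_from_gen(c(salt_bridge = 2), seed = 4)
  ours <- interaction_profile(cf$cx)
  tfx <- tempfile(fileext = ".xml")
  writeLines(synthetic_plip_xml(c(salt_bridge = 2)), tfx)
  theirs <- ingest_plip_report(tfx)
  expect_equal(sum(ours$records$type == "salt_bridge"),
               sum(theirs$records$type == "salt_bridge"))
})

test_that("text-format reports count table rows per section", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c(
    "Prediction of noncovalent interactions for PDB structure",
    "**Hydrophobic Interactions**",
    "| RESNR | RESTYPE | DIST |",
    "|-------|---------|------|",
    "| 97    | ASP     | 3.6  |",
    "| 102   | TRP     | 3.9  |",
    "**Salt Bridges**",
    "| RESNR | RESTYPE | DIST |",
    "|-------|---------|------|",
    "| 97    | ASP     | 4.6  |"), tf)
  prof <- ingest_plip_report(tf)
  expect_equal(prof$d_i, 3L)
  expect_equal(sort(unique(prof$records$type)),
               c("hydrophobic", "salt_bridge"))
})
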