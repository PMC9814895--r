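test_that("PDB parsing keeps file order and separates waters", {
  st <- parse_structure(pdb_water_line(), role = "water")
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$element, "O")
  expect_equal(st$role, "water")
  expect_equal(st$atoms$resname, "HOH")

  txt <- pdb_two_chains()
  st2 <- parse_structure(txt, role = "protein")
  # oracle: count ATOM records by line counting
  expect_equal(nrow(st2$atoms), sum(grepl("^ATOM", txt)))
  expect_equal(st2$atoms$x, (1:10) * 1.0)
  expect_equal(st2$atoms$element, rep(c("N", "C", "C", "O", "C"), 2))
})

test_that("PDB parsing errors name the offending line", {
  bad <- c(pdb_two_chains()[1],
           "ATOM      2  XX  ALA A   1       1.000   1.000   1.000  1.00  0.00          ZZ",
           "END")
  expect_error(parse_structure(bad, role = "protein"), "line 2")
  expect_error(parse_structure("REMARK nothing", role = "protein"),
               "no ATOM/HETATM")
})

test_that("SDF pose sets parse with bonds and consistent atom counts", {
  xyz <- cbind(c(0, 1.5, 3.0), 0, 0)
  blocks <- unlist(lapply(1:25, function(k)
    sdf_block(xyz + (k - 1) * 0.1, c("C", "O", "N"), title = sprintf("c%02d", k))))
  poses <- parse_ligand_poses(blocks)
  expect_length(poses, 25)
  expect_true(all(vapply(poses, function(p) nrow(p$structure$atoms), integer(1)) == 3))

  single <- parse_ligand_poses(sdf_block(xyz, c("C", "O", "N")))
  expect_length(single, 1)
  expect_equal(nrow(single[[1]]$structure$bonds), 2)  # oracle: bond-block lines

  mixed <- c(sdf_block(xyz, c("C", "O", "N")),
             sdf_block(xyz[1:2, ], c("C", "O")))
  expect_error(parse_ligand_poses(mixed), "different atom count")
})

test_that("malformed SDF counts lines are rejected", {
  bad <- sdf_block(cbind(0, 0, 0), "C")
  bad[4] <- "  x  y  0  0"
  expect_error(parse_ligand_poses(bad), "counts line")
})

test_that("MOL2 subset reader takes charges and warns about extra records", {
  txt <- c("@<TRIPOS>MOLECULE", "lig", " 2 1 0 0 0", "SMALL", "USER_CHARGES",
           "@<TRIPOS>ATOM",
           "  1 C1  0.0 0.0 0.0 C.3  1 LIG  0.12",
           "  2 O1  1.4 0.0 0.0 O.3  1 LIG -0.40",
           "@<TRIPOS>BOND", "  1 1 2 1",
           "@<TRIPOS>SUBSTRUCTURE", "  1 LIG 1")
  expect_warning(st <- parse_mol2(txt), "SUBSTRUCTURE")
  expect_equal(st$atoms$partial_charge, c(0.12, -0.40))
  expect_equal(st$atoms$element, c("C", "O"))
  expect_equal(nrow(st$bonds), 1)
})

test_that("atom typing follows the frozen rule table", {
  # ligand sp3 carbon bonded only to C -> hydrophobic aliphatic
  xyz <- cbind(c(0, 1.5, 3.0), 0, 0)
  poses <- parse_ligand_poses(sdf_block(xyz, c("C", "C", "C")))
  st <- assign_atom_types(poses[[1]]$structure, role = "ligand")
  expect_equal(st$atoms$atom_type[2], "ligand.C.aliphatic")

  # protein backbone amide N (bonded to CA and carbonyl C) -> donor
  pep <- c(
    "ATOM      1  C   ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  O   ALA A   1       0.600   1.070   0.000  1.00  0.00           O",
    "ATOM      3  N   ALA A   2       0.640  -1.170   0.000  1.00  0.00           N",
    "ATOM      4  CA  ALA A   2       2.090  -1.250   0.000  1.00  0.00           C",
    "END")
  prot <- parse_structure(pep, role = "protein")
  prot <- assign_atom_types(infer_bonds(prot), role = "protein")
  expect_equal(prot$atoms$atom_type[prot$atoms$name == "N"][1], "protein.N.donor")
  # and the carbonyl O is a pure acceptor
  expect_equal(prot$atoms$atom_type[prot$atoms$name == "O"][1], "protein.O.acceptor")
})

test_that("the vocabulary has 34 disjoint keys (16 protein + 18 ligand)", {
  p <- atom_type_vocabulary("protein")
  l <- atom_type_vocabulary("ligand")
  expect_length(p, 16)
  expect_length(l, 18)
  expect_length(union(p, l), 34)
  expect_length(intersect(p, l), 0)
  expect_equal(atom_type_vocabulary("all"), c(p, l))
})

test_that("typing is deterministic and order-independent", {
  xyz <- cbind(c(0, 1.5, 3.0, 4.5), c(0, 0.2, 0, 0.1), 0)
  el <- c("N", "C", "O", "C")
  bonds <- cbind(1:3, 2:4, 1)
  st <- parse_ligand_poses(sdf_block(xyz, el, bonds))[[1]]$structure
  t1 <- assign_atom_types(st, "ligand")$atoms$atom_type
  perm <- c(3, 1, 4, 2)
  st2 <- parse_ligand_poses(sdf_block(xyz[perm, ], el[perm],
    cbind(match(1:3, perm), match(2:4, perm), 1)))[[1]]$structure
  t2 <- assign_atom_types(st2, "ligand")$atoms$atom_type
  expect_equal(t2, t1[perm])
})

test_that("unknown elements get the generic type with a warning", {
  st <- toy_structure(cbind(c(0, 1.5), 0, 0), c("C", "Se"),
                      c(NA, NA), data.frame(i = 1, j = 2, order = 1,
                                            in_ring = FALSE))
  st$atoms$atom_type <- NA_character_
  expect_warning(typed <- assign_atom_types(st, "ligand"), "outside typing")
  expect_equal(typed$atoms$atom_type[2], "ligand.metal_other")
})

test_that("OpenDX grids round-trip exactly", {
  spec <- grid_spec(c(1, 2, 3), extent = 1, spacing = 0.5)
  g <- scalar_grid(spec, array(1, dim = c(2, 2, 2)))
  txt <- write_dx(g)
  g2 <- read_dx(text = txt)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$spec$origin, g$spec$origin)
  expect_match(txt, "delta 0.5 0 0")

  # asymmetric content survives the axis-order convention
  v <- array(seq_len(8), dim = c(2, 2, 2))
  g3 <- read_dx(text = write_dx(scalar_grid(spec, v)))
  expect_equal(g3$values, v)
})

test_that("truncated or inconsistent DX input errors", {
  spec <- grid_spec(c(0, 0, 0), extent = 1, spacing = 0.5)
  txt <- strsplit(write_dx(scalar_grid(spec, array(1, dim = c(2, 2, 2)))),
                  "\n")[[1]]
  expect_error(read_dx(text = txt[1:(length(txt) - 3)]), "body")
})

test_that("structure round trip preserves atoms, coordinates and bonds", {
  xyz <- cbind(c(0, 1.5, 2.2, 3.7), c(0, 0.3, 1.5, 1.2), c(0, 0, 0.4, 0.4))
  el <- c("C", "N", "C", "O")
  bonds <- cbind(1:3, 2:4, c(1, 1, 2))
  poses <- parse_ligand_poses(sdf_block(xyz, el, bonds))
  txt2 <- write_sdf(poses[[1]])
  back <- parse_ligand_poses(txt2)[[1]]$structure
  expect_equal(back$atoms$element, el)
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) - xyz)), 1e-3)
  expect_equal(back$bonds[, c("i", "j", "order")],
               poses[[1]]$structure$bonds[, c("i", "j", "order")])

  prot <- parse_structure(pdb_two_chains(), "protein")
  back_p <- parse_structure(write_pdb(prot), "protein")
  expect_equal(nrow(back_p$atoms), nrow(prot$atoms))
  expect_equal(back_p$atoms$element, prot$atoms$element)
  expect_lt(max(abs(back_p$atoms$x - prot$atoms$x)), 1e-3)
})
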