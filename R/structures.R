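# Molecular structure container, PDB/SDF/MOL2 readers and bond perception.

# Element table: Bondi-style vdW radii (Angstrom), covalent radii (Angstrom)
# and default valence used for implicit-hydrogen inference.
element_table <- function() {
  data.frame(
    symbol  = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
                "SE", "B", "SI", "NA", "MG", "K", "CA", "MN", "FE", "CO",
                "NI", "CU", "ZN"),
    vdw     = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98,
                1.90, 1.92, 2.10, 2.27, 1.73, 2.75, 2.31, 2.05, 2.05, 2.00,
                1.97, 1.96, 2.01),
    cov     = c(0.31, 0.76, 0.71, 0.66, 1.05, 1.07, 0.57, 1.02, 1.20, 1.39,
                1.20, 0.84, 1.11, 1.66, 1.41, 2.03, 1.76, 1.39, 1.32, 1.26,
                1.24, 1.32, 1.22),
    valence = c(1, 4, 3, 2, 2, 5, 1, 1, 1, 1, 2, 3, 4, 1, 2, 1, 2, 2, 2, 2,
                2, 2, 2),
    is_metal = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

element_lookup <- function(symbols, field) {
  tab <- element_table()
  i <- match(toupper(symbols), tab$symbol)
  tab[[field]][i]
}

new_structure <- function(atoms, bonds = NULL, role = "ligand") {
  role <- match.arg(role, c("protein", "ligand", "water"))
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), order = numeric(),
                        in_ring = logical())
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stopf("bond endpoints must be valid atom indices")
    if (any(bonds$i == bonds$j)) stopf("self-bonds are not allowed")
  }
  structure(list(atoms = atoms, bonds = bonds, role = role),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("mol_structure (%s): %d atoms (%d heavy), %d bonds\n",
              x$role, nrow(x$atoms), sum(x$atoms$is_heavy), nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x a `mol_structure`.
#' @export
n_atoms <- function(x) nrow(x$atoms)

coords_matrix <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

# Map PDB atom names to element symbols when the element column is absent.
element_from_name <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  tab <- element_table()$symbol
  out <- character(length(nm))
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "CU", "NI", "CO")
  for (k in seq_along(nm)) {
    if (two[k] %in% known2 && nchar(name[k]) >= 2 && !grepl("^[0-9]", name[k]) &&
        substr(nm[k], 1, 1) %in% c("C", "B", "F", "Z", "M", "N", "S")) {
      # two-letter elements only when the bare name is exactly the symbol
      out[k] <- if (nm[k] %in% known2) nm[k] else substr(nm[k], 1, 1)
    } else {
      out[k] <- substr(nm[k], 1, 1)
    }
    if (!(out[k] %in% tab)) out[k] <- NA_character_
  }
  out
}

#' Parse a protein, ligand or water structure from PDB text
#'
#' Reads ATOM/HETATM records (via bio3d) into a `mol_structure`. Atom order
#' follows the file. Elements come from the element column, falling back to
#' atom-name heuristics; an unresolvable element is an error naming the
#' offending line. Waters are recognized by residue name HOH/WAT and can be
#' extracted with [water_oxygens()].
#'
#' @param text PDB-format text (single string or character vector of lines).
#' @param role one of `"protein"`, `"ligand"`, `"water"`.
#' @return A `mol_structure` with an `atoms` data frame (element, coords,
#'   vdW radius, partial charge, residue info) and an empty bond table (see
#'   [infer_bonds()]).
#' @seealso [read_structure()] to read from a file path.
#' @export
parse_structure <- function(text, role = "protein") {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  rec <- grepl("^(ATOM  |HETATM)", text)
  if (!any(rec)) stopf("no ATOM/HETATM records in PDB input")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(text, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, hex = TRUE)
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  bad <- is.na(elem) | elem == ""
  elem[bad] <- element_from_name(at$elety[bad])
  known <- toupper(element_table()$symbol)
  unknown <- which(!(toupper(elem) %in% known) | is.na(elem))
  if (length(unknown)) {
    line_no <- which(rec)[unknown[1]]
    stopf("unknown element '%s' in PDB record at line %d",
          trimws(at$elesy[unknown[1]]), line_no)
  }
  elem <- toupper(elem)
  pretty <- ifelse(nchar(elem) == 2,
                   paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 2))), elem)
  atoms <- data.frame(
    index = seq_len(nrow(at)), element = pretty,
    x = at$x, y = at$y, z = at$z,
    vdw_radius = element_lookup(elem, "vdw"),
    partial_charge = 0,
    atom_type = NA_character_,
    is_heavy = elem != "H",
    name = trimws(at$elety), resname = trimws(at$resid), resno = at$resno,
    chain = ifelse(is.na(at$chain), "", at$chain),
    stringsAsFactors = FALSE)
  new_structure(atoms, role = role)
}

#' @rdname parse_structure
#' @param path path to a PDB file.
#' @export
read_structure <- function(path, role = "protein") {
  parse_structure(readLines(path, warn = FALSE), role = role)
}

#' Extract water oxygen atoms from a structure
#'
#' @param x a `mol_structure` parsed from PDB text.
#' @return A `mol_structure` with role `"water"` holding the oxygen atoms of
#'   HOH/WAT residues.
#' @export
water_oxygens <- function(x) {
  sel <- x$atoms$resname %in% c("HOH", "WAT") & x$atoms$element == "O"
  atoms <- x$atoms[sel, , drop = FALSE]
  atoms$index <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new_structure(atoms, role = "water")
}

#' Parse a set of ligand poses from SDF text
#'
#' Reads an SDF (V2000) into a list of poses. Bonds come from the bond block.
#' All molecule blocks must describe the same ligand: identical atom counts
#' and element ordering across blocks is enforced.
#'
#' @param text SDF text (single string or character vector of lines).
#' @param source pose provenance: `"docked"`, `"native"` or `"reference"`.
#' @return A list of `ligand_pose` objects, each with fields `structure`
#'   (a `mol_structure` with bonds), `pose_id` and `source`.
#' @export
parse_ligand_poses <- function(text, source = "docked") {
  source <- match.arg(source, c("docked", "native", "reference"))
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  # pre-validate counts lines: ChemmineR silently misreads malformed blocks
  ends <- grep("^\\$\\$\\$\\$", text)
  starts <- c(1L, head(ends, -1) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(text) }
  n_mol <- length(starts)
  for (k in seq_len(n_mol)) {
    block <- text[starts[k]:ends[k]]
    block <- block[block != "" | seq_along(block) <= 4]
    if (length(block) < 4) stopf("SDF block %d is truncated", k)
    cl <- block[4]
    na <- suppressWarnings(as.integer(substr(cl, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(cl, 4, 6)))
    if (is.na(na) || is.na(nb) || na < 1)
      stopf("malformed counts line in SDF block %d: '%s'", k, cl)
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  if (length(ends) && ends[length(ends)] < length(text)) text <- c(text, "$$$$")
  if (!length(grep("^\\$\\$\\$\\$", text))) text <- c(text, "$$$$")
  writeLines(text, tf)
  sdfset <- ChemmineR::read.SDFset(tf)
  poses <- vector("list", length(sdfset))
  ref_elem <- NULL
  for (k in seq_along(sdfset)) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    if (is.null(ref_elem)) ref_elem <- elem
    else if (length(elem) != length(ref_elem) || any(elem != ref_elem))
      stopf("SDF block %d has a different atom count/ordering than block 1", k)
    atoms <- data.frame(
      index = seq_along(elem), element = elem,
      x = ab[, 1], y = ab[, 2], z = ab[, 3],
      vdw_radius = element_lookup(elem, "vdw"),
      partial_charge = 0, atom_type = NA_character_,
      is_heavy = toupper(elem) != "H",
      name = rownames(ab), resname = "LIG", resno = 1L, chain = "",
      stringsAsFactors = FALSE)
    rownames(atoms) <- NULL
    bonds <- if (is.matrix(bb) && nrow(bb)) {
      ord <- as.numeric(bb[, 3])
      ord[ord == 4] <- 1.5  # aromatic
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = ord, in_ring = FALSE)
    } else NULL
    st <- new_structure(atoms, bonds, role = "ligand")
    st$bonds <- flag_ring_bonds(st)
    poses[[k]] <- ligand_pose(st, pose_id = sprintf("pose_%03d", k), source = source)
  }
  poses
}

#' @rdname parse_ligand_poses
#' @param path path to an SDF file.
#' @export
read_ligand_poses <- function(path, source = "docked") {
  parse_ligand_poses(readLines(path, warn = FALSE), source = source)
}

#' Construct a ligand pose
#'
#' @param structure a `mol_structure` with role `"ligand"`.
#' @param pose_id pose identifier (used for deterministic tie-breaking when
#'   ranking).
#' @param source `"docked"`, `"native"` or `"reference"`.
#' @export
ligand_pose <- function(structure, pose_id, source = "docked") {
  stopifnot(inherits(structure, "mol_structure"))
  structure(list(structure = structure, pose_id = as.character(pose_id),
                 source = match.arg(source, c("docked", "native", "reference"))),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("ligand_pose '%s' (%s): %d atoms\n", x$pose_id, x$source,
              nrow(x$structure$atoms)))
  invisible(x)
}

#' Read a MOL2 file (MOLECULE/ATOM/BOND subset)
#'
#' Only the `@<TRIPOS>MOLECULE`, `ATOM` and `BOND` record types are honored;
#' other sections are skipped with a warning. Partial charges are taken from
#' the ATOM records.
#'
#' @param text MOL2 text (single string or character vector of lines).
#' @return A `mol_structure` with role `"ligand"`.
#' @export
parse_mol2 <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sec <- grep("^@<TRIPOS>", text)
  if (!length(sec)) stopf("no TRIPOS records in MOL2 input")
  names(sec) <- sub("^@<TRIPOS>", "", text[sec])
  other <- setdiff(names(sec), c("MOLECULE", "ATOM", "BOND"))
  if (length(other))
    warnf("ignoring MOL2 record type(s): %s", paste(unique(other), collapse = ", "))
  section <- function(nm) {
    if (!(nm %in% names(sec))) return(character())
    i <- sec[[nm]] + 1L
    j <- sec[sec > sec[[nm]]]
    j <- if (length(j)) min(j) - 1L else length(text)
    out <- text[i:j]
    out[trimws(out) != ""]
  }
  at_lines <- section("ATOM")
  if (!length(at_lines)) stopf("MOL2 input has no ATOM section")
  fields <- strsplit(trimws(at_lines), "\\s+")
  elem <- vapply(fields, function(f) sub("\\..*$", "", f[6]), character(1))
  elem <- ifelse(nchar(elem) == 2,
                 paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 2))),
                 toupper(elem))
  charge <- vapply(fields, function(f)
    if (length(f) >= 9) suppressWarnings(as.numeric(f[9])) else NA_real_, numeric(1))
  charge[is.na(charge)] <- 0
  atoms <- data.frame(
    index = seq_along(fields), element = elem,
    x = vapply(fields, function(f) as.numeric(f[3]), numeric(1)),
    y = vapply(fields, function(f) as.numeric(f[4]), numeric(1)),
    z = vapply(fields, function(f) as.numeric(f[5]), numeric(1)),
    vdw_radius = element_lookup(elem, "vdw"),
    partial_charge = charge, atom_type = NA_character_,
    is_heavy = toupper(elem) != "H",
    name = vapply(fields, `[`, character(1), 2), resname = "LIG",
    resno = 1L, chain = "", stringsAsFactors = FALSE)
  if (anyNA(atoms$vdw_radius)) {
    k <- which(is.na(atoms$vdw_radius))[1]
    stopf("unknown element '%s' in MOL2 ATOM record %d", elem[k], k)
  }
  bd_lines <- section("BOND")
  bonds <- if (length(bd_lines)) {
    bf <- strsplit(trimws(bd_lines), "\\s+")
    ord <- vapply(bf, function(f) f[4], character(1))
    data.frame(i = vapply(bf, function(f) as.integer(f[2]), integer(1)),
               j = vapply(bf, function(f) as.integer(f[3]), integer(1)),
               order = ifelse(ord == "ar", 1.5,
                              ifelse(ord == "am", 1, suppressWarnings(as.numeric(ord)))),
               in_ring = FALSE)
  } else NULL
  st <- new_structure(atoms, bonds, role = "ligand")
  st$bonds <- flag_ring_bonds(st)
  st
}

#' Infer covalent bonds from interatomic distances
#'
#' Adds a bond between atoms whose distance is below the sum of covalent
#' radii plus `slack`. Intended for protein structures, whose file formats
#' carry no bond block; ligands should keep their SDF/MOL2 bonds.
#'
#' @param x a `mol_structure`.
#' @param slack distance tolerance in Angstrom.
#' @return The structure with its bond table filled (order 1, ring flags set).
#' @export
infer_bonds <- function(x, slack = 0.45) {
  xyz <- coords_matrix(x)
  rc <- element_lookup(toupper(x$atoms$element), "cov")
  n <- nrow(xyz)
  ii <- jj <- integer(0)
  block <- 2000L
  for (a0 in seq(1L, n, by = block)) {
    a1 <- min(a0 + block - 1L, n)
    d2 <- outer(rowSums(xyz[a0:a1, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[a0:a1, , drop = FALSE] %*% t(xyz)
    cut <- outer(rc[a0:a1], rc, "+") + slack
    hit <- which(d2 < cut^2 & d2 > 0.16, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- hit[, 1] + a0 - 1L
      gj <- hit[, 2]
      keep <- gi < gj
      ii <- c(ii, gi[keep]); jj <- c(jj, gj[keep])
    }
  }
  # never bond two waters, and keep waters unbonded to protein
  wat <- x$atoms$resname %in% c("HOH", "WAT")
  keep <- !(wat[ii] | wat[jj])
  bonds <- data.frame(i = ii[keep], j = jj[keep], order = 1, in_ring = FALSE)
  x$bonds <- bonds
  x$bonds <- flag_ring_bonds(x)
  x
}

# Adjacency list over heavy+light atoms from the bond table.
adjacency_list <- function(x) {
  n <- nrow(x$atoms)
  adj <- vector("list", n)
  b <- x$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
      adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
    }
  }
  adj
}

# Mark ring bonds: an edge is in a ring iff removing it leaves its endpoints
# connected (searched up to rings of size `max_ring`).
flag_ring_bonds <- function(x, max_ring = 8L) {
  b <- x$bonds
  if (!nrow(b)) return(b)
  adj <- adjacency_list(x)
  b$in_ring <- vapply(seq_len(nrow(b)), function(k) {
    from <- b$i[k]; to <- b$j[k]
    # BFS from `from` to `to` avoiding the direct edge, bounded depth
    seen <- rep(FALSE, length(adj))
    seen[from] <- TRUE
    frontier <- from
    depth <- 0L
    while (length(frontier) && depth < max_ring) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- adj[[v]]
        if (v == from) nb <- nb[nb != to]
        nb <- nb[!seen[nb]]
        if (to %in% nb) return(TRUE)
        seen[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    FALSE
  }, logical(1))
  b
}

# Atoms that belong to some ring (via ring bonds).
ring_atoms <- function(x) {
  b <- x$bonds
  if (!nrow(b)) return(logical(nrow(x$atoms)))
  out <- rep(FALSE, nrow(x$atoms))
  out[c(b$i[b$in_ring], b$j[b$in_ring])] <- TRUE
  out
}

#' Write a minimal PDB file for a structure
#'
#' @param x a `mol_structure`.
#' @param path output path; `NULL` returns the text.
#' @export
write_pdb <- function(x, path = NULL) {
  at <- x$atoms
  rectype <- ifelse(at$resname %in% c("HOH", "WAT", "LIG"), "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rectype, at$index %% 100000, substr(at$name, 1, 4),
                   substr(at$resname, 1, 3),
                   ifelse(at$chain == "", "A", substr(at$chain, 1, 1)),
                   at$resno %% 10000, at$x, at$y, at$z, 1, 0,
                   toupper(at$element))
  lines <- c(lines, "END")
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' Write ligand poses as an SDF (V2000) file
#'
#' @param poses a list of `ligand_pose` objects.
#' @param path output path; `NULL` returns the text.
#' @export
write_sdf <- function(poses, path = NULL) {
  if (inherits(poses, "ligand_pose")) poses <- list(poses)
  blocks <- lapply(poses, function(p) {
    at <- p$structure$atoms
    b <- p$structure$bonds
    c(p$pose_id, "  hydrascore", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(at), nrow(b)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              at$x, at$y, at$z, at$element),
      if (nrow(b)) sprintf("%3d%3d%3d  0", b$i, b$j,
                           ifelse(b$order == 1.5, 4L, as.integer(b$order))),
      "M  END", "$$$$")
  })
  txt <- unlist(blocks)
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(path)
}
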