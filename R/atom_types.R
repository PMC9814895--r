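# Frozen atom-type vocabulary and typing rules.
#
# Heavy atoms are classified into 34 types -- 16 protein and 18 ligand types,
# in the Smina/AutoDock lineage -- from element, aromaticity, bonded
# neighbors and hydrogen-bond donor/acceptor status. The exact published
# vocabularies differ slightly between tools; this table is frozen here so
# typing is reproducible without external software. Hydrogens are untyped
# and carry no density channel.

protein_type_keys <- c(
  "protein.C.aliphatic", "protein.C.polar", "protein.C.aromatic",
  "protein.N.donor", "protein.N.acceptor", "protein.N.donor_acceptor",
  "protein.N.apolar",
  "protein.O.donor", "protein.O.acceptor", "protein.O.donor_acceptor",
  "protein.S.donor", "protein.S.apolar",
  "protein.P", "protein.halogen", "protein.metal", "protein.other")

ligand_type_keys <- c(
  "ligand.C.aliphatic", "ligand.C.polar", "ligand.C.aromatic",
  "ligand.N.donor", "ligand.N.acceptor", "ligand.N.donor_acceptor",
  "ligand.N.apolar",
  "ligand.O.donor", "ligand.O.acceptor", "ligand.O.donor_acceptor",
  "ligand.S.donor", "ligand.S.apolar",
  "ligand.P", "ligand.F", "ligand.Cl", "ligand.Br", "ligand.I",
  "ligand.metal_other")

#' The frozen atom-type vocabulary
#'
#' Returns the fixed, ordered atom-type keys used as density channels:
#' 16 protein types and 18 ligand types (34 in total, disjoint). Carbon is
#' split into aliphatic/polar(aliphatic bonded to heteroatoms)/aromatic;
#' nitrogen and oxygen by hydrogen-bond donor/acceptor status; sulfur into
#' thiol-like donors and apolar; phosphorus is one type; halogens are one
#' generic protein type but four separate ligand types (F, Cl, Br, I);
#' metals/unknowns map to a generic catch-all per role.
#'
#' @param role `"protein"`, `"ligand"` or `"all"`.
#' @return Character vector of type keys, in channel order.
#' @export
atom_type_vocabulary <- function(role = c("all", "protein", "ligand")) {
  switch(match.arg(role),
         protein = protein_type_keys,
         ligand = ligand_type_keys,
         all = c(protein_type_keys, ligand_type_keys))
}

# Aromatic-atom perception. With bond orders (SDF/MOL2): an atom is aromatic
# if it sits on an order-1.5 bond, or in a 5/6-ring of C/N/O/S atoms carrying
# >= 2 double bonds. Without orders (distance-inferred protein bonds): a
# 5/6-ring of C/N atoms, each with <= 3 heavy neighbors, that is planar
# (RMS deviation from the best-fit plane < 0.15 A).
perceive_aromatic <- function(x) {
  n <- nrow(x$atoms)
  arom <- rep(FALSE, n)
  b <- x$bonds
  if (!nrow(b)) return(arom)
  arom[c(b$i[b$order == 1.5], b$j[b$order == 1.5])] <- TRUE
  rings <- find_rings(x, sizes = c(5L, 6L))
  have_orders <- any(b$order != 1)
  heavy_deg <- heavy_degree(x)
  xyz <- coords_matrix(x)
  for (ring in rings) {
    el <- toupper(x$atoms$element[ring])
    if (have_orders) {
      if (!all(el %in% c("C", "N", "O", "S"))) next
      in_ring_bond <- (b$i %in% ring) & (b$j %in% ring)
      if (sum(b$order[in_ring_bond] == 2) >= 2 || any(b$order[in_ring_bond] == 1.5))
        arom[ring] <- TRUE
    } else {
      if (!all(el %in% c("C", "N"))) next
      if (any(heavy_deg[ring] > 3)) next
      pts <- sweep(xyz[ring, , drop = FALSE], 2, colMeans(xyz[ring, , drop = FALSE]))
      sv <- svd(pts)$d
      if (sqrt(sv[3]^2 / length(ring)) < 0.15) arom[ring] <- TRUE
    }
  }
  arom
}

# Smallest rings (as atom index vectors) of the requested sizes.
find_rings <- function(x, sizes = c(3L, 4L, 5L, 6L, 7L, 8L)) {
  b <- x$bonds[x$bonds$in_ring, , drop = FALSE]
  if (!nrow(b)) return(list())
  adj <- adjacency_list(x)
  rings <- list()
  seen_keys <- character(0)
  for (k in seq_len(nrow(b))) {
    from <- b$i[k]; to <- b$j[k]
    # shortest path from->to avoiding the direct edge = smallest ring via edge
    prev <- rep(NA_integer_, length(adj))
    prev[from] <- from
    frontier <- from
    found <- FALSE
    depth <- 0L
    while (length(frontier) && !found && depth < max(sizes)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- adj[[v]]
        if (v == from) nb <- nb[nb != to]
        for (w in nb) if (is.na(prev[w])) {
          prev[w] <- v
          if (w == to) { found <- TRUE; break }
          nxt <- c(nxt, w)
        }
        if (found) break
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    if (!found) next
    path <- to
    v <- to
    while (v != from) { v <- prev[v]; path <- c(path, v) }
    if (length(path) %in% sizes) {
      key <- paste(sort(path), collapse = "-")
      if (!(key %in% seen_keys)) { rings[[length(rings) + 1L]] <- path; seen_keys <- c(seen_keys, key) }
    }
  }
  rings
}

heavy_degree <- function(x) {
  n <- nrow(x$atoms)
  deg <- integer(n)
  b <- x$bonds
  if (nrow(b)) {
    hv <- x$atoms$is_heavy
    for (k in seq_len(nrow(b))) {
      if (hv[b$i[k]] && hv[b$j[k]]) {
        deg[b$i[k]] <- deg[b$i[k]] + 1L
        deg[b$j[k]] <- deg[b$j[k]] + 1L
      }
    }
  }
  deg
}

explicit_h_count <- function(x) {
  n <- nrow(x$atoms)
  nh <- integer(n)
  b <- x$bonds
  if (nrow(b)) {
    ish <- !x$atoms$is_heavy
    for (k in seq_len(nrow(b))) {
      if (ish[b$j[k]]) nh[b$i[k]] <- nh[b$i[k]] + 1L
      if (ish[b$i[k]]) nh[b$j[k]] <- nh[b$j[k]] + 1L
    }
  }
  nh
}

#' Assign density-channel atom types
#'
#' Types every heavy atom with exactly one key from the frozen vocabulary
#' ([atom_type_vocabulary()]). Typing is a deterministic, order-independent
#' function of element, perceived aromaticity, bonded neighbors and
#' donor/acceptor status. Hydrogens stay untyped. Elements outside the
#' supported table are assigned the generic metal/other type with a warning,
#' never dropped. Ligand structures must carry bonds (from SDF/MOL2);
#' proteins get distance-inferred bonds automatically if absent.
#'
#' Donor/acceptor rules: a hydrogen count is taken from explicit H neighbors
#' plus implicit hydrogens (default valence minus bond-order sum, or minus
#' heavy degree when no orders are available). N with H is a donor; N with a
#' free lone pair (2 or fewer total connections, or a non-amide, non-aromatic
#' amine) is an acceptor. O is always an acceptor; hydroxyl-like O (with H,
#' or a terminal O on a carbon with no amide/carboxylate pattern when no H
#' are present) is donor+acceptor. S with H is a (weak) donor, otherwise
#' apolar.
#'
#' @param x a `mol_structure`.
#' @param role typing role; defaults to the structure's role.
#' @return The structure with `atoms$atom_type` filled for heavy atoms.
#' @export
assign_atom_types <- function(x, role = NULL) {
  role <- if (is.null(role)) x$role else match.arg(role, c("protein", "ligand"))
  if (role == "water") stopf("waters are not typed; they enter via hydration channels")
  at <- x$atoms
  if (role == "ligand" && !nrow(x$bonds) && sum(at$is_heavy) > 1)
    stopf("ligand typing requires a bond table (parse from SDF/MOL2)")
  if (role == "protein" && !nrow(x$bonds)) x <- infer_bonds(x)
  b <- x$bonds
  have_orders <- nrow(b) > 0 && any(b$order != 1)
  arom <- perceive_aromatic(x)
  deg <- heavy_degree(x)
  nh_exp <- explicit_h_count(x)
  el <- toupper(x$atoms$element)
  # bond-order sum over heavy neighbors (aromatic as 1.5)
  order_sum <- numeric(nrow(at))
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    if (x$atoms$is_heavy[b$i[k]] && x$atoms$is_heavy[b$j[k]]) {
      order_sum[b$i[k]] <- order_sum[b$i[k]] + b$order[k]
      order_sum[b$j[k]] <- order_sum[b$j[k]] + b$order[k]
    }
  }
  valence <- element_lookup(el, "valence")
  nh <- nh_exp
  no_h_present <- sum(nh_exp) == 0
  if (no_h_present) {
    # implicit hydrogens from valence bookkeeping
    used <- if (have_orders) ceiling(order_sum - 0.01) else deg
    nh <- pmax(0, valence - used)
    nh[arom & el == "N" & deg >= 2] <- 0  # pyridine-like ring N
  }
  adj <- adjacency_list(x)
  is_metal <- element_lookup(el, "is_metal")
  types <- rep(NA_character_, nrow(at))
  pre <- if (role == "protein") "protein." else "ligand."
  for (a in seq_len(nrow(at))) {
    if (!at$is_heavy[a]) next
    e <- el[a]
    nbrs <- adj[[a]]
    nbrs <- nbrs[x$atoms$is_heavy[nbrs]]
    nb_el <- el[nbrs]
    t <- NULL
    if (e == "C") {
      t <- if (arom[a]) "C.aromatic"
      else if (any(nb_el %in% c("N", "O", "S", "P", "F", "CL", "BR", "I"))) "C.polar"
      else "C.aliphatic"
    } else if (e == "N") {
      donor <- nh[a] >= 1
      # amide N: bonded to a carbon that carries a terminal / double-bonded O
      amide <- any(vapply(nbrs[nb_el == "C"], function(cc) {
        cnb <- adj[[cc]]
        cnb <- cnb[x$atoms$is_heavy[cnb] & cnb != a]
        any(el[cnb] == "O" & (deg[cnb] == 1 |
          (nrow(b) > 0 && any(b$order[(b$i == cc & b$j %in% cnb[el[cnb] == "O"]) |
                                       (b$j == cc & b$i %in% cnb[el[cnb] == "O"])] == 2))))
      }, logical(1)))
      total_conn <- deg[a] + nh[a]
      acceptor <- !amide && (total_conn <= 2 || (!arom[a] && total_conn == 3 && nh[a] < 3))
      t <- if (donor && acceptor) "N.donor_acceptor"
      else if (donor) "N.donor"
      else if (acceptor) "N.acceptor"
      else "N.apolar"
    } else if (e == "O") {
      # explicit H decides; otherwise a terminal O on carbon is hydroxyl only
      # when the structural context rules out carbonyl/carboxylate/amide
      hydroxyl <- nh_exp[a] >= 1 || (no_h_present && deg[a] == 0)
      if (!hydroxyl && no_h_present && deg[a] == 1 && length(nbrs) == 1 && nb_el[1] == "C") {
        cc <- nbrs[1]
        cnb <- adj[[cc]]
        cnb <- cnb[x$atoms$is_heavy[cnb] & cnb != a]
        carbonyl_like <- any(el[cnb] == "O" & deg[cnb] == 1) || any(el[cnb] == "N")
        if (have_orders) {
          dbl <- any((b$i == cc & b$j == a & b$order == 2) |
                     (b$j == cc & b$i == a & b$order == 2))
          carbonyl_like <- carbonyl_like || dbl
        }
        hydroxyl <- !carbonyl_like
      }
      t <- if (hydroxyl) "O.donor_acceptor" else "O.acceptor"
    } else if (e == "S") {
      t <- if (nh[a] >= 1) "S.donor" else "S.apolar"
    } else if (e == "P") {
      t <- "P"
    } else if (e %in% c("F", "CL", "BR", "I")) {
      t <- if (role == "protein") "halogen"
      else c(F = "F", CL = "Cl", BR = "Br", I = "I")[[e]]
    } else if (isTRUE(is_metal[a])) {
      t <- if (role == "protein") "metal" else "metal_other"
    } else {
      warnf("element '%s' outside typing vocabulary; assigned generic type", e)
      t <- if (role == "protein") "other" else "metal_other"
    }
    types[a] <- paste0(pre, t)
  }
  vocab <- atom_type_vocabulary(role)
  bad <- !is.na(types) & !(types %in% vocab)
  if (any(bad)) stopf("internal: produced type outside vocabulary: %s",
                      types[bad][1])
  x$atoms$atom_type <- types
  x
}
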