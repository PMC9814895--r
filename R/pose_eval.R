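# Pose-quality metrics: symmetry-aware RMSD in the docking frame,
# solvent-exposure-modified RMSD, contact mode score, pose labeling and
# similarity-balanced fold splitting.

heavy_subgraph <- function(st) {
  heavy <- which(st$atoms$is_heavy)
  remap <- match(seq_len(nrow(st$atoms)), heavy)
  b <- st$bonds
  keep <- b$i %in% heavy & b$j %in% heavy
  list(atoms = heavy,
       edges = cbind(remap[b$i[keep]], remap[b$j[keep]]),
       order = b$order[keep], in_ring = b$in_ring[keep])
}

# Enumerate automorphisms of the element-labeled heavy-atom bond graph.
# Backtracking with element+degree pruning; stops (with a flag) at `cap`.
graph_automorphisms <- function(st, cap = 10000L) {
  hs <- heavy_subgraph(st)
  n <- length(hs$atoms)
  el <- toupper(st$atoms$element[hs$atoms])
  adj <- vector("list", n)
  if (nrow(hs$edges)) for (k in seq_len(nrow(hs$edges))) {
    i <- hs$edges[k, 1]; j <- hs$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  deg <- lengths(adj)
  sig <- paste(el, deg)
  # order vertices: high degree first (stronger pruning)
  vorder <- order(-deg, el)
  result <- list()
  capped <- FALSE
  mapping <- integer(n)
  used <- logical(n)
  recurse <- function(pos) {
    if (capped) return()
    if (pos > n) {
      result[[length(result) + 1L]] <<- mapping
      if (length(result) >= cap) capped <<- TRUE
      return()
    }
    v <- vorder[pos]
    mapped_nb <- adj[[v]][mapping[adj[[v]]] != 0L]
    for (w in which(sig == sig[v] & !used)) {
      ok <- TRUE
      for (u in mapped_nb) if (!(mapping[u] %in% adj[[w]])) { ok <- FALSE; break }
      if (!ok) next
      mapping[v] <<- w; used[w] <<- TRUE
      recurse(pos + 1L)
      mapping[v] <<- 0L; used[w] <<- FALSE
      if (capped) return()
    }
  }
  recurse(1L)
  list(perms = result, atoms = hs$atoms, capped = capped)
}

#' Heavy-atom RMSD of a pose against reference pose(s)
#'
#' Computed in the shared docking frame (no re-superposition, since pose and
#' references share the receptor frame). The result is the minimum over all
#' supplied references and, when `use_symmetry = TRUE`, over all
#' automorphisms of the element-labeled bond graph, so that chemically
#' equivalent atom relabelings (flipped rings, symmetric substituents) do
#' not inflate the deviation. The automorphism search is capped at 10000;
#' beyond that a warning is issued and the identity mapping is used.
#'
#' @param pose a `ligand_pose` or `mol_structure`.
#' @param references a `ligand_pose`/`mol_structure` or a list of them
#'   (additional references cover symmetric binding modes).
#' @param use_symmetry minimize over bond-graph automorphisms.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(pose, references, use_symmetry = TRUE) {
  p <- if (inherits(pose, "ligand_pose")) pose$structure else pose
  if (inherits(references, "ligand_pose") || inherits(references, "mol_structure"))
    references <- list(references)
  refs <- lapply(references, function(r)
    if (inherits(r, "ligand_pose")) r$structure else r)
  heavy <- which(p$atoms$is_heavy)
  pel <- sort(toupper(p$atoms$element[heavy]))
  for (r in refs) {
    rel <- sort(toupper(r$atoms$element[r$atoms$is_heavy]))
    if (length(rel) != length(pel) || any(rel != pel))
      stopf("pose and reference have different heavy-atom composition")
  }
  pxyz <- coords_matrix(p)[heavy, , drop = FALSE]
  perms <- list(seq_along(heavy))
  if (use_symmetry) {
    au <- graph_automorphisms(p)
    if (au$capped) {
      warnf("more than 10000 bond-graph automorphisms; falling back to identity mapping")
    } else if (length(au$perms)) {
      perms <- au$perms
    }
  }
  best <- Inf
  for (r in refs) {
    rxyz <- coords_matrix(r)[r$atoms$is_heavy, , drop = FALSE]
    for (pm in perms) {
      # pm maps vertex v -> image w: atom v of the pose is compared with
      # reference position of atom pm[v]
      d2 <- rowSums((pxyz - rxyz[pm, , drop = FALSE])^2)
      best <- min(best, sqrt(mean(d2)))
    }
  }
  best
}

#' Decompose a ligand into rigid fragments
#'
#' Cuts every acyclic single bond between two non-terminal heavy atoms;
#' the connected components of the cut heavy-atom graph are the fragments
#' (rings and terminal substituents stay attached).
#'
#' @param x a `mol_structure` (ligand) with bonds.
#' @return List of integer vectors of atom indices (into `x$atoms`), one per
#'   fragment, partitioning the heavy atoms.
#' @export
fragment_decompose <- function(x) {
  lig <- if (inherits(x, "ligand_pose")) x$structure else x
  hs <- heavy_subgraph(lig)
  n <- length(hs$atoms)
  if (!n) return(list())
  deg <- integer(n)
  if (nrow(hs$edges)) for (k in seq_len(nrow(hs$edges))) {
    deg[hs$edges[k, 1]] <- deg[hs$edges[k, 1]] + 1L
    deg[hs$edges[k, 2]] <- deg[hs$edges[k, 2]] + 1L
  }
  keep <- rep(TRUE, max(1L, nrow(hs$edges)))
  if (nrow(hs$edges)) {
    keep <- !(hs$order == 1 & !hs$in_ring &
              deg[hs$edges[, 1]] > 1L & deg[hs$edges[, 2]] > 1L)
  }
  adj <- vector("list", n)
  if (nrow(hs$edges)) for (k in which(keep)) {
    i <- hs$edges[k, 1]; j <- hs$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  nc <- 0L
  for (v in seq_len(n)) {
    if (comp[v]) next
    nc <- nc + 1L
    frontier <- v
    comp[v] <- nc
    while (length(frontier)) {
      nxt <- unlist(adj[frontier])
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- nc
      frontier <- unique(nxt)
    }
  }
  lapply(seq_len(nc), function(k) hs$atoms[comp == k])
}

# Deterministic, nearly uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by deterministic sphere sampling: `n_points` points on each
#' atom's solvent-accessible sphere (radius `vdw + probe`), counting the
#' fraction not buried inside any context atom's accessible sphere.
#'
#' @param atoms a `mol_structure` (or data frame with x, y, z, vdw_radius)
#'   whose heavy atoms are measured.
#' @param context optional additional `mol_structure` providing occluding
#'   atoms (e.g. the protein around a bound ligand).
#' @param probe probe radius, Angstrom.
#' @param n_points sample points per atom.
#' @return Numeric vector of per-atom SASA (Angstrom^2) for the atoms of
#'   `atoms` (0 for hydrogens).
#' @export
shrake_rupley_sasa <- function(atoms, context = NULL, probe = 1.4,
                               n_points = 960) {
  st <- if (inherits(atoms, "ligand_pose")) atoms$structure else atoms
  xyz <- coords_matrix(st)
  rad <- st$atoms$vdw_radius
  heavy <- st$atoms$is_heavy
  occ_xyz <- xyz[heavy, , drop = FALSE]
  occ_rad <- rad[heavy] + probe
  if (!is.null(context)) {
    ctx <- if (inherits(context, "ligand_pose")) context$structure else context
    ch <- ctx$atoms$is_heavy
    occ_xyz <- rbind(occ_xyz, coords_matrix(ctx)[ch, , drop = FALSE])
    occ_rad <- c(occ_rad, ctx$atoms$vdw_radius[ch] + probe)
  }
  pts <- sphere_points(n_points)
  out <- numeric(nrow(xyz))
  for (a in which(heavy)) {
    ra <- rad[a] + probe
    sp <- sweep(pts * ra, 2, xyz[a, ], "+")
    # occluders within reach
    d2a <- (occ_xyz[, 1] - xyz[a, 1])^2 + (occ_xyz[, 2] - xyz[a, 2])^2 +
           (occ_xyz[, 3] - xyz[a, 3])^2
    near <- which(d2a < (ra + occ_rad)^2 & d2a > 1e-12)
    exposed <- rep(TRUE, n_points)
    for (o in near) {
      d2 <- (sp[, 1] - occ_xyz[o, 1])^2 + (sp[, 2] - occ_xyz[o, 2])^2 +
            (sp[, 3] - occ_xyz[o, 3])^2
      exposed <- exposed & d2 > occ_rad[o]^2
      if (!any(exposed)) break
    }
    out[a] <- 4 * pi * ra^2 * mean(exposed)
  }
  out
}

#' Solvent-exposure-modified RMSD
#'
#' Heavy-atom RMSD after excluding solvent-exposed rigid fragments. The
#' reference pose is decomposed into rigid fragments; each fragment's SASA
#' in the protein context (bound) is compared with its SASA in the unbound
#' ligand, and fragments with `SASA_bound / SASA_unbound > 0.25` are
#' considered solvent exposed and dropped from the RMSD. The reference
#' pose's exposure decides the exclusions for all poses of a system, keeping
#' the atom subset stable. If every fragment is excluded the standard RMSD
#' is returned with a warning.
#'
#' @param pose,reference `ligand_pose`s (or `mol_structure`s) with identical
#'   atom ordering.
#' @param protein the receptor `mol_structure`.
#' @param ratio_cutoff SASA-ratio exclusion threshold.
#' @param use_symmetry minimize over bond-graph automorphisms (applied on
#'   the retained atom set only when it is the full molecule; for partial
#'   sets a direct index match is used).
#' @return List with `modified_rmsd`, `standard_rmsd`, and the fragment
#'   table (`fragments`, `sasa_bound`, `sasa_unbound`, `ratio`, `excluded`).
#' @export
modified_rmsd <- function(pose, reference, protein, ratio_cutoff = 0.25,
                          use_symmetry = FALSE) {
  p <- if (inherits(pose, "ligand_pose")) pose$structure else pose
  r <- if (inherits(reference, "ligand_pose")) reference$structure else reference
  frags <- fragment_decompose(r)
  sasa_bound_atoms <- shrake_rupley_sasa(r, context = protein)
  sasa_unbound_atoms <- shrake_rupley_sasa(r)
  sb <- vapply(frags, function(f) sum(sasa_bound_atoms[f]), numeric(1))
  su <- vapply(frags, function(f) sum(sasa_unbound_atoms[f]), numeric(1))
  ratio <- ifelse(su > 0, sb / su, 0)
  excluded <- ratio > ratio_cutoff
  std <- pose_rmsd(p, r, use_symmetry = use_symmetry)
  keep_atoms <- sort(unlist(frags[!excluded]))
  if (!length(keep_atoms)) {
    warnf("all fragments are solvent exposed; falling back to standard RMSD")
    mod <- std
  } else {
    d2 <- rowSums((coords_matrix(p)[keep_atoms, , drop = FALSE] -
                   coords_matrix(r)[keep_atoms, , drop = FALSE])^2)
    mod <- sqrt(mean(d2))
  }
  list(modified_rmsd = mod, standard_rmsd = std,
       fragments = frags, sasa_bound = sb, sasa_unbound = su,
       ratio = ratio, excluded = excluded)
}

ligand_contacts <- function(lig, protein, d_c) {
  lxyz <- coords_matrix(lig)[lig$atoms$is_heavy, , drop = FALSE]
  lidx <- which(lig$atoms$is_heavy)
  pxyz <- coords_matrix(protein)[protein$atoms$is_heavy, , drop = FALSE]
  pidx <- which(protein$atoms$is_heavy)
  out <- character(0)
  for (k in seq_len(nrow(lxyz))) {
    d2 <- (pxyz[, 1] - lxyz[k, 1])^2 + (pxyz[, 2] - lxyz[k, 2])^2 +
          (pxyz[, 3] - lxyz[k, 3])^2
    hit <- which(d2 <= d_c^2)
    if (length(hit)) out <- c(out, paste(pidx[hit], lidx[k], sep = ":"))
  }
  out
}

#' Contact mode score
#'
#' Tanimoto similarity of the protein-ligand contact sets of a pose and the
#' native reference: contacts are (protein heavy atom, ligand heavy atom)
#' pairs within `d_c`; the score is `|intersection| / |union|`, in `[0, 1]`,
#' defined as 1 when both sets are empty. Symmetric in pose and reference.
#'
#' @param pose,reference `ligand_pose`s (or `mol_structure`s) sharing the
#'   protein frame and atom ordering.
#' @param protein the receptor `mol_structure`.
#' @param d_c contact distance cutoff, Angstrom.
#' @return CMS in `[0, 1]`.
#' @export
contact_mode_score <- function(pose, reference, protein, d_c = 4.5) {
  p <- if (inherits(pose, "ligand_pose")) pose$structure else pose
  r <- if (inherits(reference, "ligand_pose")) reference$structure else reference
  cp <- ligand_contacts(p, protein, d_c)
  cr <- ligand_contacts(r, protein, d_c)
  if (!length(cp) && !length(cr)) return(1.0)
  length(intersect(cp, cr)) / length(union(cp, cr))
}

#' Label a pose as native or decoy
#'
#' A pose is native iff its RMSD to the reference is strictly below the
#' threshold (2 Angstrom): a pose at exactly 2.0 is a decoy.
#'
#' @param rmsd RMSD in Angstrom (standard or modified, vectorized).
#' @param threshold native cutoff, Angstrom.
#' @return Logical.
#' @export
label_pose <- function(rmsd, threshold = 2.0) {
  stopifnot(all(rmsd >= 0))
  rmsd < threshold
}

#' Similarity-balanced fold assignment
#'
#' Single-linkage grouping of systems under the link condition
#' `sequence distance < 0.5 OR ligand similarity > 0.9`, followed by greedy
#' balancing: groups sorted by size (largest first) are assigned one by one
#' to the currently smallest fold (ties to the lowest fold index). Linked
#' systems can never land in different folds.
#'
#' @param sequence_distance,ligand_similarity square symmetric matrices over
#'   the same system ordering.
#' @param n_folds number of folds.
#' @param seq_cut,sim_cut link thresholds.
#' @return List with `fold` (integer per system), `groups` (list of system
#'   index vectors) and `fold_sizes`. Imbalance beyond one group size is
#'   reported with a message.
#' @export
split_folds <- function(sequence_distance, ligand_similarity, n_folds = 3,
                        seq_cut = 0.5, sim_cut = 0.9) {
  sd_ <- as.matrix(sequence_distance)
  ls_ <- as.matrix(ligand_similarity)
  n <- nrow(sd_)
  if (!all(dim(sd_) == c(n, n)) || !all(dim(ls_) == c(n, n)))
    stopf("similarity matrices must be square and of equal dimension")
  link <- (sd_ < seq_cut) | (ls_ > sim_cut)
  diag(link) <- FALSE
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (link[i, j]) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  ord <- order(-lengths(groups), vapply(groups, min, integer(1)))
  groups <- unname(groups[ord])
  fold <- integer(n)
  sizes <- integer(n_folds)
  for (g in groups) {
    target <- which.min(sizes)  # lowest index wins ties
    fold[g] <- target
    sizes[target] <- sizes[target] + length(g)
  }
  if (max(sizes) - min(sizes) > 1L)
    message(sprintf("fold imbalance: sizes %s", paste(sizes, collapse = "/")))
  list(fold = fold, groups = groups, fold_sizes = sizes)
}
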