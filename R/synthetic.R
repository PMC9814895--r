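# Synthetic desk-scale complexes, decoy pose sets and water trajectories
# with planted hydration structure, so the whole pipeline is testable
# without external data. Pseudo-atoms reuse the real atom-type vocabulary,
# so featurization paths are identical to real data.

#' Synthetic study specification
#'
#' Defaults mirror the study conditions the pipeline is designed around:
#' 25 poses per system with at least one native-like pose, binding-site
#' water hotspots of near-complete occupancy planted over a uniform bulk
#' background at ambient water density.
#'
#' @param n_systems number of protein-ligand systems.
#' @param n_pocket pseudo-atoms forming each binding pocket.
#' @param ligand_size heavy atoms per ligand (6-20).
#' @param n_poses poses per system (one near-native guaranteed; at least
#'   half decoys).
#' @param decoy_scale maximum decoy displacement, Angstrom.
#' @param hotspot_fraction per-frame occupancy probability of a planted
#'   hotspot.
#' @param hotspot_energy mean water interaction energy at the hotspot,
#'   kcal/mol.
#' @param hotspot_sigma positional spread of hotspot waters, Angstrom.
#' @param bulk_energy mean bulk water interaction energy, kcal/mol.
#' @param bulk_density bulk water number density, waters/Angstrom^3.
#' @param energy_sigma per-observation energy noise, kcal/mol.
#' @param n_frames trajectory frames.
#' @param extent,spacing dataset grid geometry (desk scale: 12 Angstrom at
#'   1.5 Angstrom -> 8^3 voxels).
#' @param hydration_dependent_labels if `TRUE`, native/decoy labels are a
#'   deterministic function of ligand-hotspot overlap (min heavy-atom
#'   distance to the hotspot center `<= label_cutoff`), so that geometry
#'   alone cannot separate the classes; if `FALSE`, labels are RMSD < 2.
#' @param label_cutoff overlap cutoff for hydration-dependent labels,
#'   Angstrom.
#' @param occ_amplitude,occ_sigma peak bulk-ratio amplitude and width of the
#'   analytic hotspot occupancy blob used for dataset grids.
#' @param seed master seed (mandatory; every derived quantity is
#'   deterministic given it).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_systems = 10, n_pocket = 40, ligand_size = 12,
                           n_poses = 25, decoy_scale = 4.0,
                           hotspot_fraction = 1.0, hotspot_energy = -12,
                           hotspot_sigma = 0.2, bulk_energy = -10,
                           bulk_density = 0.0334, energy_sigma = 0.5,
                           n_frames = 500, extent = 12, spacing = 1.5,
                           hydration_dependent_labels = TRUE,
                           label_cutoff = 2.0, occ_amplitude = 25,
                           occ_sigma = 1.2, seed) {
  if (missing(seed)) stopf("synthetic_spec requires a seed")
  stopifnot(n_systems >= 1, n_pocket >= 4, ligand_size >= 6,
            ligand_size <= 20, n_poses >= 1, n_frames >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Build a mol_structure from parallel vectors, with explicit types.
pseudo_structure <- function(xyz, elements, types, bonds = NULL,
                             role = "ligand", resname = "LIG") {
  n <- nrow(xyz)
  atoms <- data.frame(
    index = seq_len(n), element = as.character(elements),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw_radius = element_lookup(toupper(elements), "vdw"),
    partial_charge = rep(0, n), atom_type = as.character(types),
    is_heavy = toupper(elements) != "H",
    name = paste0(toupper(elements), seq_len(n)),
    resname = rep(resname, n), resno = seq_len(n), chain = rep("A", n),
    stringsAsFactors = FALSE)
  new_structure(atoms, bonds, role = role)
}

#' Generate one synthetic binding pocket with its native ligand pose
#'
#' The pocket is a shell of typed pseudo-atoms on a sphere cap (radius 6
#' Angstrom, opening toward +z) around the grid center; the ligand is a
#' self-avoiding chain of 6-20 typed atoms placed inside, positioned so the
#' minimum protein-ligand heavy-atom distance falls in [2.5, 4.5] Angstrom,
#' with at least one polar contact pair. Deterministic per (seed, index).
#'
#' @param spec a [synthetic_spec()].
#' @param index system index (1-based).
#' @return List with `protein` (typed `mol_structure`), `native` (a
#'   `ligand_pose`) and `center` (the pocket center).
#' @export
generate_complex <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sd_k <- derive_seed(spec$seed, index)
  with_seed(sd_k, {
    # pocket shell: directions with z below the opening cap
    n_p <- spec$n_pocket
    dirs <- matrix(rnorm(3 * n_p * 4), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    dirs <- dirs[dirs[, 3] < 0.55, , drop = FALSE][seq_len(n_p), , drop = FALSE]
    radius <- 6.0 + runif(n_p, -0.4, 0.4)
    pxyz <- dirs * radius
    p_elem <- sample(c("C", "C", "C", "N", "O"), n_p, replace = TRUE)
    p_type <- ifelse(p_elem == "C", "protein.C.aliphatic",
              ifelse(p_elem == "N", "protein.N.donor", "protein.O.acceptor"))
    # ligand: self-avoiding chain around the origin
    n_l <- spec$ligand_size
    lxyz <- matrix(0, n_l, 3)
    for (a in 2:n_l) {
      repeat {
        step <- rnorm(3)
        cand <- lxyz[a - 1, ] + 1.5 * step / sqrt(sum(step^2))
        d <- sqrt(rowSums(sweep(lxyz[seq_len(a - 1), , drop = FALSE], 2, cand)^2))
        if (min(d) > 1.2 && sqrt(sum(cand^2)) < 3.2) break
      }
      lxyz[a, ] <- cand
    }
    lxyz <- sweep(lxyz, 2, colMeans(lxyz))
    l_elem <- sample(c("C", "C", "C", "N", "O"), n_l, replace = TRUE)
    l_type <- ifelse(l_elem == "C", "ligand.C.aliphatic",
              ifelse(l_elem == "N", "ligand.N.donor", "ligand.O.acceptor"))
    # position the rigid ligand so min protein distance lands in [2.5, 4.5]
    for (iter in 1:50) {
      dmat <- sqrt(outer(rowSums(lxyz^2), rowSums(pxyz^2), "+") -
                   2 * lxyz %*% t(pxyz))
      dmin <- min(dmat)
      if (dmin >= 2.5 && dmin <= 4.5) break
      hit <- which(dmat == dmin, arr.ind = TRUE)[1, ]
      dir <- lxyz[hit[1], ] - pxyz[hit[2], ]
      dir <- dir / sqrt(sum(dir^2))
      lxyz <- sweep(lxyz, 2, dir * (3.5 - dmin), "+")
    }
    if (dmin < 2.5 || dmin > 4.5)
      stopf("could not place ligand at contact distance (system %d)", index)
    # guarantee a polar contact across the closest pair
    hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    l_elem[hit[1]] <- "N"; l_type[hit[1]] <- "ligand.N.donor"
    p_elem[hit[2]] <- "O"; p_type[hit[2]] <- "protein.O.acceptor"
    bonds <- data.frame(i = seq_len(n_l - 1), j = 2:n_l, order = 1,
                        in_ring = FALSE)
    protein <- pseudo_structure(pxyz, p_elem, p_type, role = "protein",
                                resname = "POC")
    native <- ligand_pose(pseudo_structure(lxyz, l_elem, l_type, bonds),
                          pose_id = "pose_native", source = "native")
  })
  list(protein = protein, native = native, center = c(0, 0, 0))
}

#' Generate a decoy pose set with known RMSDs
#'
#' Rigid perturbations of the native pose: rotations about the ligand
#' centroid plus translations, stratified so at least one pose is
#' native-like (RMSD < 2 by construction) and at least half are decoys
#' (RMSD > 2). Rotating about the centroid can only add to the
#' translation-induced RMSD, which makes the stratification exact. Each
#' pose's recorded RMSD is computed with [pose_rmsd()] itself.
#'
#' @param native a `ligand_pose`.
#' @param n number of poses.
#' @param scale maximum decoy displacement, Angstrom (> 2.2).
#' @param seed integer seed.
#' @return List with `poses` (list of `ligand_pose`, first is the
#'   near-native one) and `rmsd` (recorded values).
#' @export
generate_decoys <- function(native, n = 25, scale = 3.0, seed) {
  stopifnot(n >= 1)
  st <- native$structure
  ctr <- colMeans(coords_matrix(st)[st$atoms$is_heavy, , drop = FALSE])
  n_far <- if (n > 1) max(ceiling(n / 2), 1L) else 0L
  poses <- vector("list", n)
  with_seed(seed, {
    for (k in seq_len(n)) {
      if (k == 1) {
        tmag <- runif(1, 0.3, 1.5)
        ang <- 0
      } else if (k <= 1 + n_far) {
        tmag <- runif(1, 2.2, max(2.3, scale))
        ang <- runif(1, 0, pi / 5)
      } else {
        tmag <- runif(1, 0.5, max(2.3, scale))
        ang <- runif(1, 0, pi / 8)
      }
      if (scale == 0) { tmag <- 0; ang <- 0 }
      axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
      Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      ps <- st
      xyz <- sweep(coords_matrix(st), 2, ctr)
      xyz <- xyz %*% t(Rm)
      xyz <- sweep(xyz, 2, ctr + dir * tmag, "+")
      ps$atoms$x <- xyz[, 1]; ps$atoms$y <- xyz[, 2]; ps$atoms$z <- xyz[, 3]
      poses[[k]] <- ligand_pose(ps, pose_id = sprintf("pose_%03d", k))
    }
  })
  rmsds <- vapply(poses, pose_rmsd, numeric(1), references = native)
  list(poses = poses, rmsd = rmsds)
}

#' Generate a synthetic water trajectory with planted hotspots
#'
#' Per frame, each hotspot is occupied with its stated fraction; the oxygen
#' is drawn isotropically around the hotspot center (spread `sigma`) with
#' energy drawn around the planted mean. Bulk waters are placed uniformly
#' in the grid box at the bulk density with bulk-level energies, excluding
#' a 2 Angstrom shell around hotspot centers (excluded volume: a planted
#' structured water displaces bulk locally).
#'
#' @param spec a [synthetic_spec()] (supplies densities, energies, frames,
#'   seed).
#' @param grid a [grid_spec()] defining the box.
#' @param hotspots data frame with columns `x`, `y`, `z` and optionally
#'   `fraction`, `energy`, `sigma` (defaulting to the spec values); may
#'   have zero rows.
#' @param exclusion bulk exclusion radius around hotspots, Angstrom.
#' @return A [water_trajectory()].
#' @export
generate_water_trajectory <- function(spec, grid, hotspots = NULL,
                                      exclusion = 2.0) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(grid, "grid_spec"))
  if (is.null(hotspots))
    hotspots <- data.frame(x = numeric(), y = numeric(), z = numeric())
  nh <- nrow(hotspots)
  if (nh) {
    if (is.null(hotspots$fraction)) hotspots$fraction <- spec$hotspot_fraction
    if (is.null(hotspots$energy)) hotspots$energy <- spec$hotspot_energy
    if (is.null(hotspots$sigma)) hotspots$sigma <- spec$hotspot_sigma
    lo <- grid$center - grid$extent / 2
    hi <- grid$center + grid$extent / 2
    hxyz <- as.matrix(hotspots[, c("x", "y", "z")])
    if (any(hxyz < matrix(lo, nh, 3, byrow = TRUE)) ||
        any(hxyz > matrix(hi, nh, 3, byrow = TRUE)))
      stopf("hotspot outside the grid box")
  }
  vol <- grid$extent^3
  n_bulk <- round(spec$bulk_density * vol)
  lo <- grid$center - grid$extent / 2
  frames <- list()
  with_seed(derive_seed(spec$seed, 900001), {
    for (f in seq_len(spec$n_frames)) {
      xs <- list(); es <- list(); ids <- list()
      if (nh) for (h in seq_len(nh)) {
        if (runif(1) <= hotspots$fraction[h]) {
          pos <- c(hotspots$x[h], hotspots$y[h], hotspots$z[h]) +
            rnorm(3, sd = hotspots$sigma[h])
          xs[[length(xs) + 1L]] <- pos
          es[[length(es) + 1L]] <- rnorm(1, hotspots$energy[h], spec$energy_sigma)
          ids[[length(ids) + 1L]] <- 100000L + h
        }
      }
      if (n_bulk > 0) {
        bx <- matrix(runif(3 * n_bulk), ncol = 3)
        bx <- sweep(bx * grid$extent, 2, lo, "+")
        if (nh) {
          keep <- rep(TRUE, n_bulk)
          for (h in seq_len(nh)) {
            d2 <- (bx[, 1] - hotspots$x[h])^2 + (bx[, 2] - hotspots$y[h])^2 +
                  (bx[, 3] - hotspots$z[h])^2
            keep <- keep & d2 > exclusion^2
          }
          bx <- bx[keep, , drop = FALSE]
        }
        if (nrow(bx)) {
          xs[[length(xs) + 1L]] <- bx
          es[[length(es) + 1L]] <- rnorm(nrow(bx), spec$bulk_energy,
                                         spec$energy_sigma)
          ids[[length(ids) + 1L]] <- seq_len(nrow(bx))
        }
      }
      if (length(xs)) {
        cm <- do.call(rbind, lapply(xs, rbind))
        frames[[f]] <- list(coords = cm, energy = unlist(es),
                            water_id = unlist(ids))
      }
    }
  })
  nrows <- vapply(frames, function(fr) if (is.null(fr)) 0L else nrow(fr$coords),
                  integer(1))
  water_trajectory(
    frame = rep(seq_along(frames), nrows),
    water_id = unlist(lapply(frames, `[[`, "water_id")),
    coords = do.call(rbind, lapply(frames, `[[`, "coords")),
    energy = unlist(lapply(frames, `[[`, "energy")))
}

# Analytic occupancy-ratio grid: bulk background 1 plus a Gaussian blob of
# peak `amplitude` at each hotspot.
analytic_occupancy <- function(grid, hotspots, amplitude, sigma) {
  d <- grid$dims
  v <- rep(1.0, d^3)
  if (nrow(hotspots)) {
    vc <- voxel_centers(grid)
    for (h in seq_len(nrow(hotspots))) {
      d2 <- (vc[, 1] - hotspots$x[h])^2 + (vc[, 2] - hotspots$y[h])^2 +
            (vc[, 3] - hotspots$z[h])^2
      v <- v + (amplitude - 1) * exp(-d2 / (2 * sigma^2))
    }
  }
  scalar_grid(grid, array(v, dim = c(d, d, d)))
}

#' Generate a labeled synthetic pose dataset
#'
#' For each system: a pocket and native pose ([generate_complex()]), a
#' stratified pose set ([generate_decoys()]), an occupancy grid with one
#' planted hotspot (an analytic blob: the deterministic limit of a long
#' trajectory), per-pose contact mode scores, and labels. With
#' `hydration_dependent_labels` the hotspot is planted at a randomly chosen
#' pose atom and a pose is labeled native iff it overlaps the hotspot
#' (minimum heavy-atom distance `<= label_cutoff`); the choice is redrawn
#' until both classes are present. Geometry alone then cannot predict the
#' labels, while geometry plus the occupancy channel determines them
#' exactly. Without it, labels are RMSD < 2.
#'
#' @param spec a [synthetic_spec()].
#' @return List of systems, each with `protein`, `poses`, `native`,
#'   `occupancy` ([scalar_grid()]), `hotspot`, `labels`, `cms`, `rmsd`,
#'   `pose_ids`, and the shared `grid` in the attributes.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- grid_spec(c(0, 0, 0), extent = spec$extent, spacing = spec$spacing)
  systems <- vector("list", spec$n_systems)
  for (s in seq_len(spec$n_systems)) {
    cx <- generate_complex(spec, s)
    dec <- generate_decoys(cx$native, n = spec$n_poses,
                           scale = spec$decoy_scale,
                           seed = derive_seed(spec$seed, 500000 + s))
    labels <- NULL
    hotspot <- NULL
    if (spec$hydration_dependent_labels) {
      with_seed(derive_seed(spec$seed, 700000 + s), {
        for (try_k in 1:30) {
          pk <- sample.int(spec$n_poses, 1)
          stp <- dec$poses[[pk]]$structure
          hv <- which(stp$atoms$is_heavy)
          ak <- sample(hv, 1)
          hpos <- as.numeric(coords_matrix(stp)[ak, ]) + rnorm(3, sd = 0.2)
          if (any(abs(hpos) > grid$extent / 2 - 1)) next
          dmin <- vapply(dec$poses, function(p) {
            xyz <- coords_matrix(p$structure)[p$structure$atoms$is_heavy, ,
                                              drop = FALSE]
            sqrt(min((xyz[, 1] - hpos[1])^2 + (xyz[, 2] - hpos[2])^2 +
                     (xyz[, 3] - hpos[3])^2))
          }, numeric(1))
          lab <- dmin <= spec$label_cutoff
          if (any(lab) && !all(lab)) break
        }
        labels <- lab
        hotspot <- data.frame(x = hpos[1], y = hpos[2], z = hpos[3],
                              fraction = spec$hotspot_fraction,
                              energy = spec$hotspot_energy,
                              sigma = spec$hotspot_sigma)
      })
    } else {
      labels <- dec$rmsd < 2.0
      hxyz <- colMeans(coords_matrix(cx$native$structure))
      hotspot <- data.frame(x = hxyz[1], y = hxyz[2], z = hxyz[3],
                            fraction = spec$hotspot_fraction,
                            energy = spec$hotspot_energy,
                            sigma = spec$hotspot_sigma)
    }
    occ <- analytic_occupancy(grid, hotspot, spec$occ_amplitude, spec$occ_sigma)
    cms <- vapply(dec$poses, contact_mode_score, numeric(1),
                  reference = cx$native, protein = cx$protein)
    systems[[s]] <- list(system_id = sprintf("sys_%03d", s),
                         protein = cx$protein, poses = dec$poses,
                         native = cx$native, occupancy = occ,
                         hotspot = hotspot, labels = labels, cms = cms,
                         rmsd = dec$rmsd,
                         pose_ids = vapply(dec$poses, `[[`, character(1),
                                           "pose_id"))
  }
  attr(systems, "grid") <- grid
  attr(systems, "spec") <- spec
  systems
}

#' Featurize a synthetic dataset for training
#'
#' Rasterizes each system's protein once, encodes its occupancy channel,
#' rasterizes every pose and assembles the network input per pose.
#'
#' @param dataset output of [generate_dataset()].
#' @param mode `"occupancy"` (35 channels) or `"PL"` (34 channels).
#' @return List of systems in the layout [train_pose_classifier()] expects
#'   (`stacks`, `labels`, `cms`, `pose_ids`).
#' @export
featurize_dataset <- function(dataset, mode = c("occupancy", "PL")) {
  mode <- match.arg(mode)
  grid <- attr(dataset, "grid")
  lapply(dataset, function(sys) {
    pstack <- rasterize(sys$protein, grid)
    hyd <- if (mode == "occupancy")
      encode_hydration_channels(sys$occupancy, mode = "occupancy") else NULL
    stacks <- lapply(sys$poses, function(p) {
      lstack <- rasterize(p$structure, grid)
      assemble_input(pstack, lstack, hydration = hyd, mode = mode)
    })
    list(system_id = sys$system_id, stacks = stacks, labels = sys$labels,
         cms = sys$cms, pose_ids = sys$pose_ids)
  })
}

#' Deterministic manifest hash of a synthetic dataset
#'
#' MD5 over a canonical text rendering of all coordinates, energies, grids
#' and labels; identical across runs with the same seed.
#'
#' @param dataset output of [generate_dataset()].
#' @return Character MD5 hash.
#' @export
dataset_manifest_hash <- function(dataset) {
  render <- function(sys) {
    c(sys$system_id,
      sprintf("%.6f", as.numeric(coords_matrix(sys$protein))),
      unlist(lapply(sys$poses, function(p)
        sprintf("%.6f", as.numeric(coords_matrix(p$structure))))),
      sprintf("%.6f", as.numeric(sys$occupancy$values)),
      sprintf("%.6f", sys$cms), sprintf("%.6f", sys$rmsd),
      as.character(sys$labels),
      sprintf("%.6f", as.numeric(as.matrix(sys$hotspot[, c("x", "y", "z")]))))
  }
  txt <- unlist(lapply(dataset, render))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}
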