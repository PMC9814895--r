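# Grid-based hydration thermodynamics: water occupancy, pseudo-hydration
# sites, site enthalpy/entropy, QT-clustered hydration sites, normalized
# hydration channels and the grid overlap coefficient.

#' Bulk water reference
#'
#' @param density bulk water number density, waters per cubic Angstrom
#'   (default 0.0334, ambient water).
#' @param spacing grid spacing used to convert density to per-voxel
#'   occupancy: `bulk_occupancy = density * spacing^3` waters per voxel per
#'   frame.
#' @param energy mean total interaction energy of a bulk water, kcal/mol.
#'   The default (-9.533) is a typical bulk value for fixed-charge
#'   three-site water models; it is a configuration constant, not a fitted
#'   quantity, and should be matched to the force field that produced the
#'   trajectory.
#' @return A `bulk_reference` with `bulk_occupancy` and `bulk_energy`.
#' @export
bulk_reference <- function(density = 0.0334, spacing = 0.5, energy = -9.533) {
  occ <- density * spacing^3
  if (!is_scalar_number(occ) || occ <= 0) stopf("bulk occupancy must be > 0")
  structure(list(bulk_occupancy = occ, bulk_energy = energy, density = density),
            class = "bulk_reference")
}

#' Water trajectory container
#'
#' Per-frame water oxygen positions with per-water, per-frame total
#' interaction energies (water-water contributions are assumed pre-halved by
#' the producer unless `ww_halved = FALSE` and a separate water-water column
#' is supplied, in which case the loader halves it).
#'
#' @param frame integer frame index (1-based) per observation.
#' @param water_id stable integer water identifier per observation.
#' @param coords n x 3 matrix of oxygen coordinates, Angstrom.
#' @param energy per-observation interaction energy, kcal/mol.
#' @return A `water_trajectory` (data in long format plus `n_frames`).
#' @export
water_trajectory <- function(frame, water_id, coords, energy) {
  n <- length(frame)
  stopifnot(length(water_id) == n, nrow(coords) == n, length(energy) == n)
  if (n < 1 || max(frame) < 1) stopf("trajectory must contain at least one frame")
  structure(list(frame = as.integer(frame), water_id = as.integer(water_id),
                 coords = unname(as.matrix(coords)), energy = as.numeric(energy),
                 n_frames = max(as.integer(frame))),
            class = "water_trajectory")
}

#' @export
print.water_trajectory <- function(x, ...) {
  cat(sprintf("water_trajectory: %d frames, %d observations, %d distinct waters\n",
              x$n_frames, length(x$frame), length(unique(x$water_id))))
  invisible(x)
}

#' Read a water trajectory from multi-frame PDB/XYZ plus an energy table
#'
#' The trajectory is a multi-frame PDB (MODEL/ENDMDL) or concatenated XYZ
#' whose water oxygens (residue HOH/WAT for PDB, element O for XYZ) are
#' tracked; the energy table is TSV with columns `frame water_id energy_kcal`
#' and an optional `# ww_halved: true|false` header. If `ww_halved` is false
#' a fourth column `ww_energy` must be present; half of it is subtracted to
#' undo double counting of water-water interactions.
#'
#' @param traj_path path to the trajectory file.
#' @param energy_path path to the energy TSV.
#' @return A [water_trajectory()].
#' @export
read_water_trajectory <- function(traj_path, energy_path) {
  lines <- readLines(traj_path, warn = FALSE)
  is_pdb <- any(grepl("^(ATOM  |HETATM|MODEL)", lines))
  obs <- if (is_pdb) {
    mk <- grep("^MODEL", lines)
    bounds <- if (length(mk)) c(mk, length(lines) + 1L) else c(1L, length(lines) + 1L)
    out <- list()
    for (f in seq_len(length(bounds) - 1L)) {
      seg <- lines[bounds[f]:(bounds[f + 1L] - 1L)]
      rec <- seg[grepl("^(ATOM  |HETATM)", seg)]
      resn <- trimws(substr(rec, 18, 20))
      name <- trimws(substr(rec, 13, 16))
      sel <- resn %in% c("HOH", "WAT") & grepl("^O", name)
      if (!any(sel)) next
      out[[f]] <- data.frame(
        frame = f,
        water_id = as.integer(trimws(substr(rec[sel], 23, 26))),
        x = as.numeric(substr(rec[sel], 31, 38)),
        y = as.numeric(substr(rec[sel], 39, 46)),
        z = as.numeric(substr(rec[sel], 47, 54)))
    }
    do.call(rbind, out)
  } else {
    # concatenated XYZ frames: natoms line, comment, atom lines
    out <- list(); i <- 1L; f <- 0L
    while (i <= length(lines)) {
      na <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(na)) stopf("malformed XYZ frame header at line %d", i)
      f <- f + 1L
      rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + na)]), "\\s+")
      el <- vapply(rows, `[`, character(1), 1)
      sel <- toupper(el) %in% c("O", "OW")
      out[[f]] <- data.frame(
        frame = f, water_id = which(sel),
        x = vapply(rows[sel], function(r) as.numeric(r[2]), numeric(1)),
        y = vapply(rows[sel], function(r) as.numeric(r[3]), numeric(1)),
        z = vapply(rows[sel], function(r) as.numeric(r[4]), numeric(1)))
      i <- i + 2L + na
    }
    do.call(rbind, out)
  }
  if (is.null(obs) || !nrow(obs)) stopf("no water oxygens found in trajectory")
  hdr <- readLines(energy_path, n = 5L, warn = FALSE)
  ww_halved <- TRUE
  hl <- grep("^#\\s*ww_halved:", hdr, value = TRUE)
  if (length(hl)) ww_halved <- grepl("true", tolower(hl[1]))
  en <- read.table(energy_path, header = TRUE, sep = "\t", comment.char = "#")
  names(en)[1:3] <- c("frame", "water_id", "energy_kcal")
  if (!ww_halved) {
    if (!("ww_energy" %in% names(en)))
      stopf("ww_halved is false but no ww_energy column is present")
    en$energy_kcal <- en$energy_kcal - 0.5 * en$ww_energy
  }
  m <- merge(obs, en[, c("frame", "water_id", "energy_kcal")],
             by = c("frame", "water_id"), sort = FALSE)
  if (nrow(m) != nrow(obs))
    warnf("%d water observations lack energies and were dropped",
          nrow(obs) - nrow(m))
  m <- m[order(m$frame, m$water_id), ]
  water_trajectory(m$frame, m$water_id, as.matrix(m[, c("x", "y", "z")]),
                   m$energy_kcal)
}

#' Accumulate water occupancy onto the grid
#'
#' Each oxygen visits exactly one voxel per frame (its containing cell); the
#' voxel value is the visit count normalized by `n_frames * bulk_occupancy`,
#' i.e. an occupancy ratio relative to bulk (1 = bulk-like).
#'
#' @param traj a [water_trajectory()].
#' @param spec a [grid_spec()].
#' @param bulk a [bulk_reference()]; its `bulk_occupancy` must correspond to
#'   `spec$spacing`.
#' @return A [scalar_grid()] of bulk-ratio occupancies.
#' @export
accumulate_occupancy <- function(traj, spec, bulk) {
  stopifnot(inherits(traj, "water_trajectory"), inherits(bulk, "bulk_reference"))
  if (traj$n_frames < 1) stopf("trajectory has zero frames")
  idx3 <- point_to_voxel(traj$coords, spec)
  ok <- !is.na(idx3[, 1]) & !is.na(idx3[, 2]) & !is.na(idx3[, 3])
  d <- spec$dims
  counts <- numeric(d^3)
  if (any(ok)) {
    lin <- voxel_linear_index(idx3[ok, , drop = FALSE], spec)
    tb <- tabulate(lin, nbins = d^3)
    counts <- tb
  }
  ratio <- counts / (traj$n_frames * bulk$bulk_occupancy)
  scalar_grid(spec, array(ratio, dim = c(d, d, d)))
}

#' Detect pseudo-hydration sites
#'
#' Every voxel whose occupancy ratio is strictly greater than 2 (twice the
#' bulk occupancy) becomes a pseudo-hydration site. A site's contributing
#' observations are all (water, frame) pairs whose oxygen lies within a
#' closed 1 Angstrom ball around the voxel center, throughout the
#' trajectory.
#'
#' @param occupancy a [scalar_grid()] from [accumulate_occupancy()].
#' @param traj the same [water_trajectory()].
#' @param bulk the [bulk_reference()] used for the occupancy grid.
#' @param radius contribution radius, Angstrom.
#' @return A data frame with one row per site: voxel indices, center
#'   position, occupancy ratio, number of contributing observations, and a
#'   `contributors` list-column of observation indices into the trajectory.
#' @export
detect_pseudo_sites <- function(occupancy, traj, bulk, radius = 1.0) {
  stopifnot(inherits(occupancy, "scalar_grid"))
  spec <- occupancy$spec
  hit <- which(occupancy$values > 2.0, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(ix = integer(), iy = integer(), iz = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      occupancy_ratio = numeric(), n_contributing = integer(),
                      contributors = I(list())))
  }
  centers <- cbind(spec$origin[1] + (hit[, 1] - 1) * spec$spacing,
                   spec$origin[2] + (hit[, 2] - 1) * spec$spacing,
                   spec$origin[3] + (hit[, 3] - 1) * spec$spacing)
  contributors <- vector("list", nrow(hit))
  for (k in seq_len(nrow(hit))) {
    d2 <- (traj$coords[, 1] - centers[k, 1])^2 +
          (traj$coords[, 2] - centers[k, 2])^2 +
          (traj$coords[, 3] - centers[k, 3])^2
    contributors[[k]] <- which(d2 <= radius^2)
  }
  out <- data.frame(ix = hit[, 1], iy = hit[, 2], iz = hit[, 3],
                    x = centers[, 1], y = centers[, 2], z = centers[, 3],
                    occupancy_ratio = occupancy$values[hit],
                    n_contributing = lengths(contributors))
  out$contributors <- I(contributors)
  out[order(-out$occupancy_ratio), ]
}

# Boltzmann constant in kcal/mol/K.
KB_KCAL <- 0.0019872

#' Pseudo-site desolvation thermodynamics
#'
#' For each site, the desolvation enthalpy is the mean interaction energy of
#' its contributing (water, frame) observations minus the bulk energy:
#' `dH = <E> - E_bulk` (kcal/mol). The entropic term is a translational
#' estimator: `-T dS = + T k KL(q || uniform)` where `q` is the empirical
#' distribution of contributing oxygen positions over a fixed 0.25 Angstrom
#' sub-binning of the 1 Angstrom site sphere (k = 0.0019872 kcal/mol/K,
#' T = 300 K by default). A perfectly ordered site (all observations in one
#' sub-bin of m) gives `T k ln(m)`; a uniform spread gives 0. Rotational
#' entropy is not estimated (recorded in the returned attributes).
#'
#' @param traj a [water_trajectory()].
#' @param sites data frame from [detect_pseudo_sites()].
#' @param bulk a [bulk_reference()].
#' @param temperature Kelvin.
#' @param radius site sphere radius, Angstrom (must match detection).
#' @param sub_bin sub-bin edge, Angstrom.
#' @return `sites` with columns `dH` and `minus_TdS` added (kcal/mol).
#' @export
site_thermodynamics <- function(traj, sites, bulk, temperature = 300,
                                radius = 1.0, sub_bin = 0.25) {
  if (!nrow(sites)) {
    sites$dH <- numeric(0); sites$minus_TdS <- numeric(0)
    return(sites)
  }
  # sub-bins: cells of a sub_bin grid covering [-r, r]^3 whose centers lie
  # within the site sphere
  nsb <- as.integer(ceiling(2 * radius / sub_bin))
  ax <- -radius + (seq_len(nsb) - 0.5) * sub_bin
  cent <- as.matrix(expand.grid(ax, ax, ax))
  inside <- rowSums(cent^2) <= radius^2
  bin_map <- cumsum(inside)          # cell -> index among inside bins
  m <- sum(inside)
  dH <- minus_TdS <- numeric(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    obs <- sites$contributors[[k]]
    if (!length(obs))
      stopf("site at voxel (%d,%d,%d) has no contributing waters",
            sites$ix[k], sites$iy[k], sites$iz[k])
    dH[k] <- mean(traj$energy[obs]) - bulk$bulk_energy
    rel <- sweep(traj$coords[obs, , drop = FALSE], 2,
                 c(sites$x[k], sites$y[k], sites$z[k]))
    cell <- pmin(pmax(floor((rel + radius) / sub_bin), 0), nsb - 1)
    lin <- cell[, 1] + nsb * cell[, 2] + nsb^2 * cell[, 3] + 1
    bins <- bin_map[lin]
    bins[!inside[lin]] <- NA
    # observations on the closed sphere boundary can land in a corner cell
    # whose center is outside; fold them into the nearest inside bin
    if (anyNA(bins)) {
      for (w in which(is.na(bins))) {
        d2 <- rowSums(sweep(cent[inside, , drop = FALSE], 2, rel[w, ])^2)
        bins[w] <- which.min(d2)
      }
    }
    q <- tabulate(bins, nbins = m) / length(bins)
    nzq <- q[q > 0]
    minus_TdS[k] <- temperature * KB_KCAL * sum(nzq * log(nzq * m))
  }
  sites$dH <- dH
  sites$minus_TdS <- minus_TdS
  attr(sites, "entropy_estimator") <-
    "translational KL vs uniform over 0.25 A sub-bins; rotational entropy not included"
  sites
}

#' QT-cluster hydration sites from an occupancy grid
#'
#' Greedy quality-threshold clustering of occupancy peaks: repeatedly take
#' the maximum-occupancy voxel with ratio > 2, found a hydration site of
#' radius 1 Angstrom at its center, remove all voxels within 2 Angstrom, and
#' stop when no qualifying voxel remains. Sites come out ordered by
#' decreasing peak occupancy and are pairwise at least 2 Angstrom apart.
#'
#' @param occupancy a [scalar_grid()] of bulk-ratio occupancies.
#' @param min_ratio occupancy-ratio threshold (strict).
#' @param exclusion removal radius around an accepted peak, Angstrom.
#' @return Data frame of site centers (`x`, `y`, `z`), `peak_occupancy` and
#'   fixed `radius` (1 Angstrom).
#' @export
cluster_hydration_sites <- function(occupancy, min_ratio = 2.0, exclusion = 2.0) {
  spec <- occupancy$spec
  v <- as.vector(occupancy$values)
  cand <- which(v > min_ratio)
  if (!length(cand)) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      peak_occupancy = numeric(), radius = numeric()))
  }
  cc <- voxel_centers(spec)[cand, , drop = FALSE]
  val <- v[cand]
  alive <- rep(TRUE, length(cand))
  out <- list()
  while (any(alive)) {
    k <- which(alive)[which.max(val[alive])]
    ctr <- cc[k, ]
    out[[length(out) + 1L]] <- data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
                                          peak_occupancy = val[k], radius = 1.0)
    d2 <- (cc[, 1] - ctr[1])^2 + (cc[, 2] - ctr[2])^2 + (cc[, 3] - ctr[3])^2
    alive <- alive & d2 > exclusion^2
  }
  do.call(rbind, out)
}

#' Hydration thermodynamics grids
#'
#' Runs the grid-based pipeline: occupancy accumulation, pseudo-site
#' detection and site thermodynamics, then scatters dH and -TdS back onto
#' the grid (non-zero only at pseudo-site voxels, i.e. where occupancy
#' exceeds twice bulk).
#'
#' @inheritParams accumulate_occupancy
#' @param temperature Kelvin.
#' @return List of class `hydration_thermo_grids` with [scalar_grid()]s
#'   `occupancy`, `enthalpy`, `entropy_term`, plus the `sites` table.
#' @export
hydration_thermo_grids <- function(traj, spec, bulk, temperature = 300) {
  occ <- accumulate_occupancy(traj, spec, bulk)
  sites <- detect_pseudo_sites(occ, traj, bulk)
  sites <- site_thermodynamics(traj, sites, bulk, temperature = temperature)
  d <- spec$dims
  dh <- ts <- array(0, dim = c(d, d, d))
  if (nrow(sites)) {
    lin <- (sites$ix - 1L) + d * (sites$iy - 1L) + d^2 * (sites$iz - 1L) + 1L
    dh[lin] <- sites$dH
    ts[lin] <- sites$minus_TdS
  }
  structure(list(occupancy = occ, enthalpy = scalar_grid(spec, dh),
                 entropy_term = scalar_grid(spec, ts), sites = sites),
            class = "hydration_thermo_grids")
}

#' Encode hydration grids as normalized network channels
#'
#' All hydration inputs are squashed into `[0, 1)` with a hyperbolic
#' tangent. Occupancy mode produces one channel `tanh(ratio / s_occ)`.
#' Thermo mode produces three: `Hminus = tanh(|dH|/s_H)` where `dH < 0`
#' (favorable enthalpy, taken as absolute value), `Hplus = tanh(dH/s_H)`
#' where `dH > 0`, and `TS = tanh(|TdS|/s_S)`.
#'
#' @param grids a `hydration_thermo_grids` (thermo mode) or a
#'   [scalar_grid()] of occupancy ratios (occupancy mode).
#' @param mode `"occupancy"` or `"thermo"`.
#' @param s_occ,s_H,s_S tanh scales: bulk-ratio units, kcal/mol, kcal/mol.
#' @return A [channel_stack()] with 1 or 3 channels.
#' @export
encode_hydration_channels <- function(grids, mode = c("occupancy", "thermo"),
                                      s_occ = 2.0, s_H = 1.0, s_S = 1.0) {
  mode <- match.arg(mode)
  if (mode == "occupancy") {
    occ <- if (inherits(grids, "hydration_thermo_grids")) grids$occupancy else grids
    stopifnot(inherits(occ, "scalar_grid"))
    if (!all(is.finite(occ$values))) stopf("non-finite occupancy values")
    d <- occ$spec$dims
    data <- array(tanh(occ$values / s_occ), dim = c(1L, d, d, d))
    return(channel_stack(occ$spec, data, "water.occupancy"))
  }
  stopifnot(inherits(grids, "hydration_thermo_grids"))
  dh <- grids$enthalpy$values
  ts <- grids$entropy_term$values
  if (!all(is.finite(dh)) || !all(is.finite(ts))) stopf("non-finite grid values")
  d <- grids$enthalpy$spec$dims
  data <- array(0, dim = c(3L, d, d, d))
  data[1, , , ] <- ifelse(dh < 0, tanh(abs(dh) / s_H), 0)
  data[2, , , ] <- ifelse(dh > 0, tanh(dh / s_H), 0)
  data[3, , , ] <- tanh(abs(ts) / s_S)
  channel_stack(grids$enthalpy$spec, data,
                c("water.Hminus", "water.Hplus", "water.TS"))
}

#' Overlap coefficient between two non-negative grids
#'
#' `OC = sum_i min(p1_i / sum(p1), p2_i / sum(p2))`: 1 for identical
#' distributions, 0 for disjoint supports. Inputs must be non-negative with
#' positive total mass; signed fields (e.g. energy grids) should be
#' pre-transformed (`abs()`, or split by sign) before comparison, since the
#' normalization presumes a distribution.
#'
#' @param grid1,grid2 [scalar_grid()]s on the same spec (or plain numeric
#'   vectors/arrays of equal length).
#' @return The overlap coefficient in `[0, 1]`.
#' @export
#' @examples
#' overlap_coefficient(c(1, 1, 0), c(0, 1, 1)) # 0.5
overlap_coefficient <- function(grid1, grid2) {
  v1 <- if (inherits(grid1, "scalar_grid")) grid1$values else grid1
  v2 <- if (inherits(grid2, "scalar_grid")) grid2$values else grid2
  if (inherits(grid1, "scalar_grid") && inherits(grid2, "scalar_grid") &&
      !same_spec(grid1$spec, grid2$spec))
    stopf("grids must share the same grid_spec")
  if (length(v1) != length(v2)) stopf("grids must have equal length")
  if (any(v1 < 0) || any(v2 < 0))
    stopf("overlap coefficient requires non-negative grids; pre-transform signed fields (abs or split by sign)")
  s1 <- sum(v1); s2 <- sum(v2)
  if (s1 <= 0 || s2 <= 0) stopf("grids must have positive total mass")
  sum(pmin(v1 / s1, v2 / s2))
}
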