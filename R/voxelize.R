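# Voxel featurization: atom-density channels and the assembled network input.

#' Piece-wise continuous atom density kernel
#'
#' The dimensionless density contributed by an atom of van der Waals radius
#' `R` at distance `r` from a voxel center:
#' `exp(-2 r^2 / R^2)` on `[0, R)`, the matching quadratic
#' `4 r^2/(e^2 R^2) - 12 r/(e^2 R) + 9/e^2` on `[R, 1.5 R)`, and 0 beyond.
#' Both branches equal `1/e^2` at `r = R` and the quadratic reaches 0 at
#' `r = 1.5 R`, so the kernel is continuous everywhere and supported on
#' `[0, 1.5 R)`.
#'
#' @param r distance(s) from the atom center, Angstrom (vectorized).
#' @param R van der Waals radius of the atom type, Angstrom (> 0).
#' @return Density value(s) in `[0, 1]`.
#' @export
#' @examples
#' density_kernel(0, 1.7)            # 1
#' density_kernel(1.7, 1.7)          # 1/e^2
#' density_kernel(1.5 * 1.7, 1.7)    # 0
density_kernel <- function(r, R) {
  if (!is_scalar_number(R) || R <= 0) stopf("vdW radius R must be > 0")
  if (any(r < 0)) stopf("distances must be non-negative")
  .density_kernel_cpp(as.numeric(r), R)
}

#' Multi-channel voxel image
#'
#' A `channel_stack` holds named density channels on a shared [grid_spec()].
#' Internally the data is a single numeric array of dim
#' `c(n_channels, dims, dims, dims)` (channel-fastest), the layout consumed
#' by the network.
#'
#' @param spec a [grid_spec()].
#' @param data array of dim `c(length(channel_names), dims, dims, dims)`.
#' @param channel_names ordered, unique channel names.
#' @export
channel_stack <- function(spec, data, channel_names) {
  stopifnot(inherits(spec, "grid_spec"))
  d <- spec$dims
  nc <- length(channel_names)
  if (anyDuplicated(channel_names)) stopf("channel names must be unique")
  if (!identical(dim(data), as.integer(c(nc, d, d, d))))
    stopf("data must have dim c(%d, %d, %d, %d)", nc, d, d, d)
  structure(list(spec = spec, data = data, channel_names = channel_names),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("channel_stack: %d channels on a %d^3 grid (%.3g A spacing)\n",
              length(x$channel_names), x$spec$dims, x$spec$spacing))
  nz <- apply(x$data, 1, function(v) any(v != 0))
  cat(sprintf("  non-empty channels: %d (%s%s)\n", sum(nz),
              paste(head(x$channel_names[nz], 4), collapse = ", "),
              if (sum(nz) > 4) ", ..." else ""))
  invisible(x)
}

#' Number of channels in a stack
#' @param stack a [channel_stack()].
#' @export
n_channels <- function(stack) length(stack$channel_names)

#' Extract one channel as a scalar grid
#' @param stack a [channel_stack()].
#' @param name channel name or integer position.
#' @export
get_channel <- function(stack, name) {
  k <- if (is.numeric(name)) as.integer(name) else match(name, stack$channel_names)
  if (is.na(k) || k < 1 || k > n_channels(stack)) stopf("no such channel: %s", name)
  d <- stack$spec$dims
  scalar_grid(stack$spec, array(stack$data[k, , , ], dim = c(d, d, d)))
}

#' Rasterize typed atoms into per-type density channels
#'
#' Each heavy atom contributes [density_kernel()] density, parameterized by
#' its vdW radius, to the channel of its atom type; same-type contributions
#' sum. Channels for unused vocabulary types are present and all-zero, so a
#' stack always has the full 16 (protein) or 18 (ligand) channels. Atoms
#' whose kernel support lies outside the grid contribute nothing.
#'
#' @param x a typed `mol_structure` (see [assign_atom_types()]).
#' @param spec a [grid_spec()].
#' @return A [channel_stack()] with the role's full type vocabulary.
#' @export
rasterize <- function(x, spec) {
  stopifnot(inherits(x, "mol_structure"), inherits(spec, "grid_spec"))
  vocab <- atom_type_vocabulary(x$role)
  heavy <- x$atoms$is_heavy
  if (any(heavy & is.na(x$atoms$atom_type)))
    stopf("untyped heavy atom(s); run assign_atom_types() first")
  sel <- which(heavy)
  d <- spec$dims
  if (length(sel)) {
    ti <- match(x$atoms$atom_type[sel], vocab)
    vec <- .rasterize_cpp(coords_matrix(x)[sel, , drop = FALSE],
                          x$atoms$vdw_radius[sel], ti, length(vocab),
                          spec$origin, spec$spacing, d)
  } else {
    vec <- numeric(length(vocab) * d^3)
  }
  channel_stack(spec, array(vec, dim = c(length(vocab), d, d, d)), vocab)
}

#' Random rigid augmentation of a protein/pose pair
#'
#' Applies one uniform random 3D rotation about `center` and one random
#' translation drawn uniformly from the ball of radius `max_translation`
#' (default 2 Angstrom), rigidly and identically to the protein and the
#' pose, so that their relative geometry is exactly preserved. Deterministic
#' per seed. Hydration grids stay on the fixed grid frame; augmentation is
#' applied before rasterization so images are re-rendered, not interpolated.
#'
#' @param protein a `mol_structure`.
#' @param pose a `ligand_pose` (or `mol_structure`).
#' @param seed integer seed (required: augmentation must be reproducible).
#' @param center rotation center (typically the grid center).
#' @param max_translation maximum translation magnitude, Angstrom.
#' @return List with transformed `protein`, `pose`, and the applied
#'   `rotation` (3x3) and `translation` (length 3).
#' @export
augment_pose <- function(protein, pose, seed, center = c(0, 0, 0),
                         max_translation = 2.0) {
  if (missing(seed) || is.null(seed)) stopf("augmentation requires a seed")
  draws <- with_seed(seed, list(q = rnorm(4), u = runif(1), dir = rnorm(3)))
  q <- draws$q / sqrt(sum(draws$q^2))  # uniform unit quaternion -> uniform SO(3)
  Rm <- quaternion_to_matrix(q)
  tr <- draws$dir / sqrt(sum(draws$dir^2)) * max_translation * draws$u^(1 / 3)
  apply_rigid <- function(st) {
    xyz <- coords_matrix(st)
    xyz <- sweep(xyz, 2, center)
    xyz <- xyz %*% t(Rm)
    xyz <- sweep(xyz, 2, center + tr, "+")
    st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
    st
  }
  pose_out <- pose
  if (inherits(pose, "ligand_pose")) pose_out$structure <- apply_rigid(pose$structure)
  else pose_out <- apply_rigid(pose)
  list(protein = apply_rigid(protein), pose = pose_out,
       rotation = Rm, translation = tr)
}

quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Assemble the multi-channel network input
#'
#' Concatenates, in a fixed documented order, the 16 protein type channels,
#' the 18 ligand type channels, then the hydration channels (1 in occupancy
#' mode, 3 in thermo mode, none in PL mode), then any probe channels. The
#' resulting channel count is 34 (PL), 35 (occupancy) or 37 (thermo), plus
#' the probe channels when supplied.
#'
#' @param protein_stack [channel_stack()] from a protein (16 channels).
#' @param ligand_stack [channel_stack()] from a ligand pose (18 channels).
#' @param hydration hydration channels as returned by
#'   [encode_hydration_channels()] (a [channel_stack()]), or `NULL`.
#' @param probes optional probe-extremum [channel_stack()] (see
#'   [probe_channels()]).
#' @param mode `"PL"`, `"occupancy"` or `"thermo"`.
#' @return A [channel_stack()] with all channels on the shared grid.
#' @export
assemble_input <- function(protein_stack, ligand_stack, hydration = NULL,
                           probes = NULL, mode = c("occupancy", "thermo", "PL")) {
  mode <- match.arg(mode)
  parts <- list(protein_stack, ligand_stack)
  if (mode != "PL") {
    if (is.null(hydration)) stopf("mode '%s' requires hydration channels", mode)
    want <- if (mode == "occupancy") 1L else 3L
    if (n_channels(hydration) != want)
      stopf("mode '%s' expects %d hydration channel(s), got %d",
            mode, want, n_channels(hydration))
    parts <- c(parts, list(hydration))
  }
  if (!is.null(probes)) parts <- c(parts, list(probes))
  spec <- parts[[1]]$spec
  for (p in parts[-1]) if (!same_spec(spec, p$spec))
    stopf("all stacks must share the same grid_spec")
  nm <- unlist(lapply(parts, `[[`, "channel_names"))
  d <- spec$dims
  data <- array(0, dim = c(length(nm), d, d, d))
  off <- 0L
  for (p in parts) {
    k <- n_channels(p)
    data[off + seq_len(k), , , ] <- p$data
    off <- off + k
  }
  channel_stack(spec, data, nm)
}
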