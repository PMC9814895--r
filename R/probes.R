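# Probe interaction fields: Coulomb fields of unit probes, their favorable
# extrema, and Gaussian channels centered on the extrema. These channels
# stand in for anisotropic electrostatics (halogen bonds, directional
# hydrogen bonds) that atom-centered isotropic densities cannot encode;
# anisotropy can be emulated upstream with off-center virtual charges via
# the pluggable charge model.

COULOMB_KCAL <- 332.06  # kcal * Angstrom / (mol * e^2)

#' Probe interaction field on the grid
#'
#' Voxel value = `sum_atoms probe_sign * q_atom * C / max(r, r_min)` with
#' `C = 332.06 kcal A / (mol e^2)` and a 0.5 Angstrom singularity clamp.
#' Negative values are favorable (attractive) interactions of the probe.
#'
#' @param x a `mol_structure` with partial charges (or see `charge_model`).
#' @param spec a [grid_spec()].
#' @param probe_sign +1 (positive probe) or -1 (negative probe).
#' @param charge_model optional function `(structure) -> numeric charges`
#'   replacing the stored partial charges.
#' @param r_min clamp distance, Angstrom.
#' @return A `probe_field`: a [scalar_grid()] with attributes `probe_sign`
#'   and `target` (the structure's role).
#' @export
probe_interaction_field <- function(x, spec, probe_sign = +1,
                                    charge_model = NULL, r_min = 0.5) {
  stopifnot(probe_sign %in% c(-1, 1))
  q <- if (is.null(charge_model)) x$atoms$partial_charge else charge_model(x)
  if (all(q == 0)) message("probe field: all partial charges are zero")
  d <- spec$dims
  vals <- numeric(d^3)
  vc <- voxel_centers(spec)
  xyz <- coords_matrix(x)
  for (a in seq_len(nrow(xyz))) {
    if (q[a] == 0) next
    r <- sqrt((vc[, 1] - xyz[a, 1])^2 + (vc[, 2] - xyz[a, 2])^2 +
              (vc[, 3] - xyz[a, 3])^2)
    vals <- vals + probe_sign * q[a] * COULOMB_KCAL / pmax(r, r_min)
  }
  g <- scalar_grid(spec, array(vals, dim = c(d, d, d)))
  attr(g, "probe_sign") <- probe_sign
  attr(g, "target") <- x$role
  g
}

#' Favorable extrema of a probe field
#'
#' Finds voxels that are strict minima of the interaction energy (most
#' favorable for the probe) within their 26-voxel neighborhood, with
#' magnitude at least `tau`. Results are sorted by magnitude, descending.
#'
#' @param field a `probe_field` from [probe_interaction_field()].
#' @param tau noise floor, kcal/mol: extrema with `|value| < tau` are
#'   discarded.
#' @return Data frame with `x`, `y`, `z`, `magnitude` (kcal/mol, >= 0),
#'   `probe_sign`, `target`.
#' @export
extract_extrema <- function(field, tau = 5.0) {
  stopifnot(inherits(field, "scalar_grid"))
  v <- field$values
  d <- field$spec$dims
  hits <- list()
  for (iz in 1:d) for (iy in 1:d) for (ix in 1:d) {
    val <- v[ix, iy, iz]
    if (val >= 0 || abs(val) < tau) next
    nb <- v[max(1, ix - 1):min(d, ix + 1),
            max(1, iy - 1):min(d, iy + 1),
            max(1, iz - 1):min(d, iz + 1)]
    if (sum(nb < val) == 0 && sum(nb == val) == 1)  # strict minimum
      hits[[length(hits) + 1L]] <- c(ix, iy, iz, abs(val))
  }
  if (!length(hits)) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      magnitude = numeric(), probe_sign = numeric(),
                      target = character()))
  }
  h <- do.call(rbind, hits)
  out <- data.frame(
    x = field$spec$origin[1] + (h[, 1] - 1) * field$spec$spacing,
    y = field$spec$origin[2] + (h[, 2] - 1) * field$spec$spacing,
    z = field$spec$origin[3] + (h[, 3] - 1) * field$spec$spacing,
    magnitude = h[, 4],
    probe_sign = attr(field, "probe_sign") %||% NA_real_,
    target = attr(field, "target") %||% NA_character_)
  out[order(-out$magnitude), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian channels centered on probe extrema
#'
#' Each extremum contributes `exp(-d^2 / (2 sigma^2))` with amplitude 1 at
#' its center and a width that grows with the interaction magnitude:
#' `sigma = sigma0 * (0.5 + tanh(magnitude / E0))`. One channel per
#' (probe sign, target) combination; contributions within a channel sum.
#'
#' @param extrema data frame from [extract_extrema()] (possibly rbind-ed
#'   over probe signs and targets).
#' @param spec a [grid_spec()].
#' @param sigma0 base width, Angstrom.
#' @param E0 magnitude scale, kcal/mol.
#' @return A [channel_stack()] with 4 channels:
#'   `probe.plus.protein`, `probe.minus.protein`, `probe.plus.ligand`,
#'   `probe.minus.ligand` (all-zero channels kept).
#' @export
probe_channels <- function(extrema, spec, sigma0 = 1.0, E0 = 10.0) {
  d <- spec$dims
  keys <- c("probe.plus.protein", "probe.minus.protein",
            "probe.plus.ligand", "probe.minus.ligand")
  data <- array(0, dim = c(4L, d, d, d))
  if (nrow(extrema)) {
    vc <- voxel_centers(spec)
    for (k in seq_len(nrow(extrema))) {
      key <- sprintf("probe.%s.%s",
                     if (extrema$probe_sign[k] > 0) "plus" else "minus",
                     extrema$target[k])
      ch <- match(key, keys)
      if (is.na(ch)) stopf("unknown probe channel key '%s'", key)
      sigma <- sigma0 * (0.5 + tanh(extrema$magnitude[k] / E0))
      d2 <- (vc[, 1] - extrema$x[k])^2 + (vc[, 2] - extrema$y[k])^2 +
            (vc[, 3] - extrema$z[k])^2
      data[ch, , , ] <- data[ch, , , ] + array(exp(-d2 / (2 * sigma^2)),
                                               dim = c(d, d, d))
    }
  }
  channel_stack(spec, data, keys)
}
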