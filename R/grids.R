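#' Binding-site grid geometry
#'
#' A `grid_spec` describes the cubic voxel grid on which all channels live:
#' a cube of edge `extent` centered at `center`, divided into cubic voxels of
#' edge `spacing`. Voxels are cell-centered: the center of voxel
#' `(k1, k2, k3)` (0-based) lies at `center - extent/2 + (k + 0.5) * spacing`.
#' The defaults (24 Angstrom box, 0.5 Angstrom spacing, 48 voxels per axis)
#' are the standard binding-site image used by the pose classifier.
#'
#' @param center numeric length-3, grid center in Angstrom.
#' @param extent edge length of the cubic box in Angstrom.
#' @param spacing voxel edge in Angstrom; must divide `extent` to within
#'   rounding (`dims = round(extent / spacing)`).
#' @return An object of class `grid_spec` with fields `center`, `extent`,
#'   `spacing`, `dims` and `origin` (center of the first voxel).
#' @export
#' @examples
#' spec <- grid_spec(c(0, 0, 0))
#' spec$dims # 48
grid_spec <- function(center = c(0, 0, 0), extent = 24, spacing = 0.5) {
  stopifnot(length(center) == 3, all(is.finite(center)))
  if (!is_scalar_number(spacing) || spacing <= 0) stopf("spacing must be > 0")
  if (!is_scalar_number(extent) || extent <= 0) stopf("extent must be > 0")
  dims <- as.integer(round(extent / spacing))
  if (abs(dims * spacing - extent) > 1e-6)
    stopf("extent (%g) is not an integer multiple of spacing (%g)", extent, spacing)
  origin <- center - extent / 2 + spacing / 2
  structure(list(center = as.numeric(center), extent = extent,
                 spacing = spacing, dims = dims, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d^3 voxels, %.3g A spacing, %.3g A extent, center (%.2f, %.2f, %.2f)\n",
              x$dims, x$spacing, x$extent, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

same_spec <- function(a, b, tol = 1e-6) {
  a$dims == b$dims && abs(a$spacing - b$spacing) < tol &&
    all(abs(a$center - b$center) < tol)
}

#' Voxel center coordinates
#'
#' @param spec a [grid_spec()].
#' @return A `dims^3 x 3` matrix of voxel-center coordinates, voxels ordered
#'   with the first axis fastest (matching R array linearization).
#' @export
voxel_centers <- function(spec) {
  ax <- lapply(1:3, function(d) spec$origin[d] + (seq_len(spec$dims) - 1) * spec$spacing)
  cbind(rep(ax[[1]], times = spec$dims^2),
        rep(rep(ax[[2]], each = spec$dims), times = spec$dims),
        rep(ax[[3]], each = spec$dims^2))
}

# Map points (n x 3) to 1-based voxel array indices; NA if outside the grid.
point_to_voxel <- function(points, spec) {
  idx <- matrix(NA_integer_, nrow(points), 3)
  for (d in 1:3) {
    k <- floor((points[, d] - (spec$origin[d] - spec$spacing / 2)) / spec$spacing)
    k[k < 0 | k >= spec$dims] <- NA
    idx[, d] <- as.integer(k) + 1L
  }
  idx
}

voxel_linear_index <- function(idx3, spec) {
  (idx3[, 1] - 1L) + spec$dims * (idx3[, 2] - 1L) +
    spec$dims^2 * (idx3[, 3] - 1L) + 1L
}

#' Scalar field on a voxel grid
#'
#' @param spec a [grid_spec()].
#' @param values numeric array of dim `c(dims, dims, dims)`, or a scalar that
#'   is recycled.
#' @return An object of class `scalar_grid` with fields `spec` and `values`.
#' @export
scalar_grid <- function(spec, values = 0) {
  stopifnot(inherits(spec, "grid_spec"))
  d <- spec$dims
  if (length(values) == 1L) values <- array(values, dim = c(d, d, d))
  if (!identical(dim(values), c(d, d, d)))
    stopf("values must be a %d^3 array", d)
  if (!all(is.finite(values))) stopf("grid values must be finite")
  structure(list(spec = spec, values = values), class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("scalar_grid: %d^3 voxels, range [%.4g, %.4g], sum %.6g\n",
              x$spec$dims, min(v), max(v), sum(v)))
  invisible(x)
}

#' Read and write scalar grids as OpenDX text
#'
#' `write_dx()` serializes a [scalar_grid()] into the OpenDX "regular
#' positions, regular connections" scalar format used by molecular grid tools;
#' `read_dx()` parses it back. Round trips preserve origin and spacing exactly
#' as printed and data to the printed precision (17 significant digits, i.e.
#' lossless for doubles).
#'
#' @param grid a [scalar_grid()].
#' @param path file path; for `write_dx`, `NULL` returns the text invisibly.
#' @return `read_dx()` returns a [scalar_grid()]; its `spec` is reconstructed
#'   from the DX origin/delta and carries the DX node-centered origin as the
#'   first voxel center.
#' @export
write_dx <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "scalar_grid"))
  spec <- grid$spec
  d <- spec$dims
  o <- spec$origin
  s <- spec$spacing
  head <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d, d, d),
    sprintf("origin %.10g %.10g %.10g", o[1], o[2], o[3]),
    sprintf("delta %.10g 0 0", s),
    sprintf("delta 0 %.10g 0", s),
    sprintf("delta 0 0 %.10g", s),
    sprintf("object 2 class gridconnections counts %d %d %d", d, d, d),
    sprintf("object 3 class array type double rank 0 items %d data follows", d^3))
  # DX convention: last index (z) varies fastest
  v <- aperm(grid$values, c(3, 2, 1))
  vals <- formatC(as.vector(v), format = "g", digits = 17)
  n <- length(vals)
  pad <- ceiling(n / 3) * 3 - n
  if (pad > 0) vals <- c(vals, rep("", pad))
  body <- apply(matrix(vals, ncol = 3, byrow = TRUE), 1, paste, collapse = " ")
  body <- trimws(body)
  txt <- c(head, body, 'attribute "dep" string "positions"')
  if (is.null(path)) return(invisible(paste(txt, collapse = "\n")))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_dx
#' @param text DX text as a character vector of lines (alternative to `path`).
#' @export
read_dx <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  } else readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions", lines, value = TRUE)
  if (length(gp) == 0) stopf("not an OpenDX grid: no gridpositions object")
  counts <- as.integer(strsplit(sub(".*counts\\s+", "", gp[1]), "\\s+")[[1]])
  if (length(counts) != 3 || any(is.na(counts))) stopf("malformed counts line")
  if (length(unique(counts)) != 1L)
    stopf("only cubic grids are supported (counts %s)", paste(counts, collapse = "x"))
  og <- grep("^origin", lines, value = TRUE)
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", og[1])), "\\s+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  deltas <- t(vapply(dl, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]), numeric(3)))
  spacing <- deltas[1, 1]
  if (!isTRUE(all.equal(diag(c(spacing, spacing, spacing)), unname(deltas), tolerance = 1e-9)))
    stopf("only axis-aligned cubic deltas are supported")
  istart <- grep("data follows", lines)
  if (length(istart) == 0) stopf("malformed DX: no data section")
  n_items <- as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1", lines[istart[1]]))
  if (is.na(n_items) || n_items != prod(counts))
    stopf("DX header item count does not match grid dimensions")
  body <- lines[(istart[1] + 1):length(lines)]
  body <- body[!grepl("^(object|attribute)", body)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != n_items)
    stopf("DX body has %d values, header declares %d", length(vals), n_items)
  d <- counts[1]
  v <- aperm(array(vals, dim = c(d, d, d)), c(3, 2, 1))
  spec <- grid_spec(center = origin + (d - 1) * spacing / 2,
                    extent = d * spacing, spacing = spacing)
  # keep the printed origin exactly (guards against rounding in center math)
  spec$origin <- origin
  scalar_grid(spec, v)
}
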