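# Shared in-code fixtures: tiny PDB/SDF texts and toy structures.

pdb_water_line <- function() {
  c("HETATM    1  O   HOH A   1       5.000   5.000   5.000  1.00  0.00           O",
    "END")
}

pdb_two_chains <- function() {
  # 10 atoms over 2 chains, deterministic coordinates
  lines <- character(0)
  k <- 0
  for (ch in c("A", "B")) for (i in 1:5) {
    k <- k + 1
    el <- c("N", "C", "C", "O", "C")[i]
    nm <- c("N", "CA", "C", "O", "CB")[i]
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      k, nm, ch, i, k * 1.0, k * 0.5, -k * 0.25, el))
  }
  c(lines, "END")
}

# A chain molecule as SDF text; elements and coords given per atom.
sdf_block <- function(coords, elements, bonds = NULL, title = "mol") {
  if (is.null(bonds) && length(elements) > 1)
    bonds <- cbind(seq_len(length(elements) - 1), 2:length(elements), 1)
  nb <- if (is.null(bonds)) 0 else nrow(bonds)
  c(title, "  fixture", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", length(elements), nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], elements),
    if (nb) sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2], bonds[, 3]),
    "M  END", "$$$$")
}

# Typed toy structure directly from coordinates (no file round trip).
toy_structure <- function(xyz, elements, types, bonds = NULL, role = "ligand") {
  hydrascore:::pseudo_structure(as.matrix(xyz), elements, types, bonds,
                                role = role)
}

# Benzene-like ring: 6 aromatic carbons on a hexagon, ring bonds.
benzene_like <- function(rot = 0, role = "ligand") {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6] + rot
  xyz <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1),
                      order = c(2, 1, 2, 1, 2, 1), in_ring = TRUE)
  toy_structure(xyz, rep("C", 6), rep("ligand.C.aromatic", 6), bonds, role)
}

# Dense cage of pseudo protein atoms on a sphere (for burial tests).
cage_structure <- function(center, radius = 3.5, n = 80) {
  pts <- hydrascore:::sphere_points(n) * radius
  pts <- sweep(pts, 2, center, "+")
  toy_structure(pts, rep("C", n), rep("protein.C.aliphatic", n),
                role = "protein")
}

# Brute-force z+ rule on a dense layer (independent oracle).
lrp_linear_brute <- function(x, w, b, R_upper) {
  n_in <- length(x); n_out <- length(R_upper)
  R_low <- numeric(n_in)
  for (j in seq_len(n_out)) {
    pre <- sum(x * w[, j]) + b[j]
    Rj <- if (pre >= 0) R_upper[j] else 0
    if (Rj == 0) next
    zp <- x * pmax(w[, j], 0)
    if (sum(zp) <= 0) next
    for (i in seq_len(n_in)) R_low[i] <- R_low[i] + zp[i] / sum(zp) * Rj
  }
  R_low
}

# Unroll a 3^3 conv into its dense matrix by applying it to basis vectors.
conv_as_dense <- function(w, b, Cin, Cout, D) {
  n_in <- Cin * D^3
  n_out <- Cout * D^3
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_in)) {
    e <- numeric(n_in); e[i] <- 1
    A[, i] <- hydrascore:::.conv3d_fwd_cpp(e, as.numeric(w), numeric(Cout),
                                           Cin, Cout, D)
  }
  A
}
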