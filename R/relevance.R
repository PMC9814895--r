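# Deep-Taylor layer-wise relevance propagation with the z+ rule, plus
# aggregation of voxel relevance to atoms and hydration categories.
#
# The backward pass starts from the native-class output and redistributes
# relevance layer by layer so that (on zero-bias networks) the total is
# conserved and every relevance value is non-negative. At a linear map the
# z+ rule distributes a node's relevance over its inputs in proportion to
# x_i * max(w_ij, 0); nodes with negative pre-activation are gated to zero.

#' z+ rule relevance propagation through a dense linear layer
#'
#' Given input activations `x >= 0`, weights `w` (n_in x n_out), biases `b`
#' and upper-layer relevances `R_upper >= 0`, each output node j first keeps
#' its relevance only if its pre-activation `sum_i x_i w_ij + b_j` is
#' non-negative (gating), then distributes it over inputs proportionally to
#' `z_ij^+ = x_i * max(w_ij, 0)`. A node whose positive-part denominator is
#' zero distributes nothing (its relevance vanishes, counted in the
#' `dropped` attribute).
#'
#' @param x input activations (length n_in, non-negative).
#' @param w weight matrix, n_in x n_out.
#' @param b biases, length n_out.
#' @param R_upper relevances of the output nodes (length n_out,
#'   non-negative).
#' @param gate apply the pre-activation gating (disable only when seeding
#'   relevance at the network output, where the start relevance is the
#'   non-negative softmax value itself).
#' @return Lower-layer relevances (length n_in, non-negative).
#' @export
relevance_backprop_linear <- function(x, w, b, R_upper, gate = TRUE) {
  w <- as.matrix(w)
  if (any(x < 0)) stopf("z+ rule requires non-negative input activations")
  if (any(R_upper < 0)) stopf("relevances must be non-negative")
  stopifnot(nrow(w) == length(x), ncol(w) == length(R_upper),
            length(b) == length(R_upper))
  pre <- drop(crossprod(w, x)) + b
  R_up <- R_upper
  if (gate) R_up[pre < 0] <- 0
  zplus <- x * pmax(w, 0)          # n_in x n_out
  denom <- colSums(zplus)
  active <- denom > 0 & R_up > 0
  dropped <- sum(R_up[denom <= 0 & R_up > 0])
  R_low <- numeric(length(x))
  if (any(active))
    R_low <- drop(zplus[, active, drop = FALSE] %*%
                  (R_up[active] / denom[active]))
  attr(R_low, "dropped") <- dropped
  R_low
}

#' z+ rule relevance propagation through a 3D convolution
#'
#' The convolution is treated as a shared-weight linear map: z+ rule
#' redistribution per receptive field, with the same pre-activation gating
#' and zero-denominator handling as the dense case.
#'
#' @param x input tensor values (channel-fastest vector or array, Cin x D^3).
#' @param w conv weights, dim `c(Cin, Cout, 3, 3, 3)`.
#' @param b biases, length Cout.
#' @param R_upper upper relevances (Cout x D^3).
#' @param dims input edge length D.
#' @return Lower-layer relevances (Cin x D^3 vector).
#' @export
relevance_backprop_conv <- function(x, w, b, R_upper, dims) {
  dm <- dim(w)
  if (any(x < 0)) stopf("z+ rule requires non-negative input activations")
  .lrp_conv_cpp(as.numeric(x), as.numeric(w), b, as.numeric(R_upper),
                dm[1], dm[2], dims)
}

#' Relevance propagation through 2x2x2 max pooling
#'
#' Winner-takes-all: each pooled output's relevance is routed entirely to
#' the maximal input voxel of its window; exact ties split the relevance
#' equally among the tied inputs.
#'
#' @param x pre-pooling activations (C x D^3).
#' @param R_upper pooled-layer relevances (C x (D/2)^3).
#' @param channels channel count C.
#' @param dims input edge length D.
#' @return Relevances on the pre-pooling layer (C x D^3 vector).
#' @export
relevance_backprop_pool <- function(x, R_upper, channels, dims) {
  .lrp_pool_cpp(as.numeric(x), as.numeric(R_upper), channels, dims)
}

#' Explain a pose prediction by relevance propagation
#'
#' Runs a forward pass, seeds the native-class softmax output value as the
#' start relevance on the native logit, and propagates it backward through
#' the fully connected layer, the pooling stages and the convolutions down
#' to the input channels. All relevances are non-negative; on zero-bias
#' networks the per-layer totals are conserved (biases absorb relevance, so
#' conservation is only guaranteed without them).
#'
#' @param net a `hydranet`.
#' @param input a [channel_stack()] or input tensor.
#' @param start `"softmax"` (default: native-class probability) or
#'   `"logit"` (pre-softmax native output, clamped at 0 from below).
#' @return A `relevance_map`: list with `input_relevance` (array C x D^3,
#'   same layout as the input tensor), `channel_names` (if the input was a
#'   stack), `layer_sums` (total relevance entering each stage, output to
#'   input), `start_relevance` and `dropped` (relevance lost at
#'   zero-denominator nodes).
#' @export
explain <- function(net, input, start = c("softmax", "logit")) {
  start <- match.arg(start)
  if (any(!is.finite(coef(net)))) stopf("network has non-finite weights")
  fwd <- nn_forward(net, input, keep = TRUE)
  R_start <- if (start == "softmax") fwd$p_native else max(fwd$logits[2], 0)
  layer_sums <- numeric(0)
  dropped <- 0
  # FC layer: relevance enters at the native logit (no gating of the seed
  # node itself; the seed is already the non-negative classifier output)
  R_out <- c(0, R_start, 0)
  R_feat <- relevance_backprop_linear(fwd$feat, net$fc$w, net$fc$b, R_out,
                                      gate = FALSE)
  dropped <- dropped + attr(R_feat, "dropped")
  layer_sums <- c(start = R_start, fc_in = sum(R_feat))
  R_cur <- as.numeric(R_feat)
  for (k in rev(seq_along(net$layers))) {
    rec <- fwd$layers[[k]]
    d_in <- rec$d_in
    # through pooling (R on pooled -> R on post-ReLU activations)
    R_post <- relevance_backprop_pool(rec$post, R_cur, rec$cout, d_in)
    below <- if (k == 1) fwd$input else fwd$layers[[k - 1]]$pooled
    R_cur <- relevance_backprop_conv(below, net$layers[[k]]$w,
                                     net$layers[[k]]$b, R_post, d_in)
    layer_sums <- c(layer_sums, setNames(sum(R_cur), sprintf("conv%d_in", k)))
  }
  out <- list(input_relevance = array(R_cur, dim = dim(stack_to_tensor(input))),
              layer_sums = layer_sums, start_relevance = R_start,
              dropped = dropped)
  if (inherits(input, "channel_stack")) {
    out$channel_names <- input$channel_names
    out$spec <- input$spec
  }
  class(out) <- "relevance_map"
  out
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("relevance_map: start %.4f, input total %.4f, min %.2g\n",
              x$start_relevance, sum(x$input_relevance), min(x$input_relevance)))
  invisible(x)
}

#' Aggregate voxel relevance to atoms and hydration categories
#'
#' Atom relevance: each voxel's relevance in an atom-type channel is shared
#' among the atoms of that type in proportion to their density contribution
#' at the voxel. Water-channel relevance is split into four geometric
#' categories relative to the pose: `replaced` (voxel within `d_replaced`
#' of a ligand heavy atom), `interface_mediating` (within `d_mediating` of
#' both a ligand and a protein polar heavy atom, and not replaced),
#' `first_shell` (within `d_shell` of the ligand, and neither), `other`.
#'
#' @param map a `relevance_map` from [explain()] on a stack input.
#' @param protein,pose typed `mol_structure` / `ligand_pose` on the same
#'   grid frame.
#' @param d_replaced,d_mediating,d_shell category distance cutoffs,
#'   Angstrom.
#' @return A `relevance_summary`: per-atom relevance tables for protein and
#'   ligand, per-category water relevance, and `fractions` (protein, ligand,
#'   water categories) summing to 1 when the total is positive.
#' @export
aggregate_relevance <- function(map, protein, pose,
                                d_replaced = 2.0, d_mediating = 3.5,
                                d_shell = 4.5) {
  if (is.null(map$channel_names))
    stopf("explain() must be run on a channel_stack to aggregate")
  spec <- map$spec
  lig <- if (inherits(pose, "ligand_pose")) pose$structure else pose
  vc <- voxel_centers(spec)
  nch <- length(map$channel_names)
  d <- spec$dims
  rel <- map$input_relevance
  atom_rel <- function(st) {
    heavy <- which(st$atoms$is_heavy)
    out <- numeric(nrow(st$atoms))
    xyz <- coords_matrix(st)
    for (ch in seq_len(nch)) {
      nm <- map$channel_names[ch]
      members <- heavy[st$atoms$atom_type[heavy] %in% nm]
      if (!length(members)) next
      rch <- as.vector(rel[ch, , , ])
      nz <- which(rch > 0)
      if (!length(nz)) next
      dens <- matrix(0, length(nz), length(members))
      for (m in seq_along(members)) {
        a <- members[m]
        r <- sqrt((vc[nz, 1] - xyz[a, 1])^2 + (vc[nz, 2] - xyz[a, 2])^2 +
                  (vc[nz, 3] - xyz[a, 3])^2)
        dens[, m] <- density_kernel(r, st$atoms$vdw_radius[a])
      }
      tot <- rowSums(dens)
      ok <- tot > 0
      if (any(ok)) {
        share <- dens[ok, , drop = FALSE] / tot[ok]
        out[members] <- out[members] + drop(crossprod(share, rch[nz][ok]))
      }
    }
    out
  }
  protein_rel <- atom_rel(protein)
  ligand_rel <- atom_rel(lig)
  # water channels: occupancy/thermo channels
  water_ch <- grep("^water\\.", map$channel_names)
  cat_rel <- c(replaced = 0, interface_mediating = 0, first_shell = 0, other = 0)
  if (length(water_ch)) {
    lxyz <- coords_matrix(lig)[lig$atoms$is_heavy, , drop = FALSE]
    polar <- protein$atoms$is_heavy &
      toupper(protein$atoms$element) %in% c("N", "O", "S")
    pxyz <- coords_matrix(protein)[polar, , drop = FALSE]
    min_d <- function(ref) {
      if (!nrow(ref)) return(rep(Inf, nrow(vc)))
      out <- rep(Inf, nrow(vc))
      for (a in seq_len(nrow(ref)))
        out <- pmin(out, (vc[, 1] - ref[a, 1])^2 + (vc[, 2] - ref[a, 2])^2 +
                         (vc[, 3] - ref[a, 3])^2)
      sqrt(out)
    }
    dl <- min_d(lxyz)
    dp <- min_d(pxyz)
    category <- ifelse(dl <= d_replaced, "replaced",
                ifelse(dl <= d_mediating & dp <= d_mediating, "interface_mediating",
                ifelse(dl <= d_shell, "first_shell", "other")))
    for (ch in water_ch) {
      rch <- as.vector(rel[ch, , , ])
      for (cg in names(cat_rel))
        cat_rel[cg] <- cat_rel[cg] + sum(rch[category == cg])
    }
  }
  total <- sum(protein_rel) + sum(ligand_rel) + sum(cat_rel)
  fractions <- c(protein = sum(protein_rel), ligand = sum(ligand_rel), cat_rel)
  if (total > 0) fractions <- fractions / total
  structure(list(protein_atom_relevance = protein_rel,
                 ligand_atom_relevance = ligand_rel,
                 water_category_relevance = cat_rel,
                 fractions = fractions, total = total),
            class = "relevance_summary")
}

#' @export
print.relevance_summary <- function(x, ...) {
  cat("relevance fractions:\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-20s %6.2f%%\n", nm, 100 * x$fractions[nm]))
  invisible(x)
}
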