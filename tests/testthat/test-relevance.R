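test_that("dense z+ rule reproduces the worked examples", {
  # proportional redistribution: z+ = (0.5, 2) -> (0.2, 0.8)
  r <- relevance_backprop_linear(c(1, 2), cbind(c(0.5, 1)), 0, 1)
  expect_equal(as.numeric(r), c(0.2, 0.8))
  expect_equal(sum(r), 1.0)  # conservation of the node's relevance
  # negative pre-activation gates the node (sum = -3.5 < 0)
  r2 <- relevance_backprop_linear(c(1, 2), cbind(c(0.5, -2)), 0, 1)
  expect_equal(as.numeric(r2), c(0, 0))
  # zero pre-activation propagates; negative weights are clipped
  r3 <- relevance_backprop_linear(c(1, 1), cbind(c(1, -1)), 0, 1)
  expect_equal(as.numeric(r3), c(1, 0))
  expect_error(relevance_backprop_linear(c(-1, 1), cbind(c(1, 1)), 0, 1),
               "non-negative")
})

test_that("dense z+ rule matches a brute-force evaluation on random layers", {
  set.seed(11)
  for (k in 1:25) {
    x <- abs(rnorm(8))
    w <- matrix(rnorm(32), 8, 4)
    b <- rnorm(4)
    R <- abs(rnorm(4))
    expect_equal(as.numeric(relevance_backprop_linear(x, w, b, R)),
                 lrp_linear_brute(x, w, b, R), tolerance = 1e-10)
  }
})

test_that("conv z+ rule equals the dense rule on the unrolled linear map", {
  set.seed(12)
  for (k in 1:5) {
    Cin <- 2; Cout <- 2; D <- 2
    w <- array(rnorm(Cin * Cout * 27), dim = c(Cin, Cout, 3, 3, 3))
    b <- rnorm(Cout)
    x <- abs(rnorm(Cin * D^3))
    Rup <- abs(rnorm(Cout * D^3))
    dense <- conv_as_dense(w, b, Cin, Cout, D)
    b_dense <- rep(b, times = D^3)[rep(seq_len(Cout), D^3) +
                                   Cout * rep(0:(D^3 - 1), each = Cout) * 0]
    # bias per output node in channel-fastest order
    b_dense <- b[rep(seq_len(Cout), D^3)]
    ref <- lrp_linear_brute(x, t(dense), b_dense, Rup)
    got <- relevance_backprop_conv(x, w, b, Rup, D)
    expect_equal(as.numeric(got), ref, tolerance = 1e-10)
  }
})

test_that("max-pool relevance is winner-takes-all with equal tie splits", {
  # single channel, one 2x2x2 window
  x <- c(2, 5, 0, 0, 0, 0, 0, 0)
  r <- relevance_backprop_pool(x, 1, channels = 1, dims = 2)
  expect_equal(r, c(0, 1, 0, 0, 0, 0, 0, 0))
  x2 <- c(4, 4, 0, 0, 0, 0, 0, 0)
  r2 <- relevance_backprop_pool(x2, 1, channels = 1, dims = 2)
  expect_equal(r2, c(0.5, 0.5, 0, 0, 0, 0, 0, 0))
})

test_that("relevance is conserved per layer on zero-bias networks", {
  set.seed(13)
  worst <- 0
  n_live <- 0
  for (k in 1:40) {
    net <- build_network(3, 4, c(4, 4), seed = k)  # zero-bias init
    x <- array(abs(rnorm(3 * 64)), dim = c(3, 4, 4, 4))
    m <- explain(net, x)
    expect_true(all(m$input_relevance >= 0))
    # conservation holds along live positive paths; a network whose ReLUs
    # silence every feature, or whose native logit receives no positive
    # contribution, carries no positive evidence to decompose
    feat <- hydrascore:::nn_forward(net, x, keep = TRUE)$feat
    live <- any(feat * pmax(net$fc$w[, 2], 0) > 0)
    if (live) {
      n_live <- n_live + 1
      rel_err <- max(abs(m$layer_sums - m$start_relevance)) / m$start_relevance
      worst <- max(worst, rel_err)
    }
  }
  expect_gte(n_live, 20)
  expect_lt(worst, 1e-5)
})

test_that("gated nodes contribute no downstream relevance", {
  set.seed(14)
  x <- abs(rnorm(6))
  w <- matrix(rnorm(18), 6, 3)
  b <- c(0, -1e6, 0)   # node 2 always negatively pre-activated
  R <- c(1, 1, 1)
  r_all <- relevance_backprop_linear(x, w, b, R)
  r_wo <- relevance_backprop_linear(x, w[, -2, drop = FALSE], b[-2], R[-2])
  expect_equal(as.numeric(r_all), as.numeric(r_wo))
})

test_that("an identity-like conv routes all relevance to the active voxel", {
  net <- build_network(1, 2, c(1), seed = 1)
  w <- array(0, dim = c(1, 1, 3, 3, 3))
  w[1, 1, 2, 2, 2] <- 1  # pass-through kernel
  net$layers[[1]]$w <- w
  net$fc$w <- matrix(c(0, 1, 0), 1, 3)  # native logit reads the pooled max
  x <- array(0, dim = c(1, 2, 2, 2))
  x[1, 2, 1, 2] <- 3
  m <- explain(net, x)
  expect_equal(sum(m$input_relevance > 0), 1)
  expect_gt(m$input_relevance[1, 2, 1, 2], 0)
  expect_equal(sum(m$input_relevance), m$start_relevance, tolerance = 1e-10)
})

test_that("relevance aggregates to atoms and water categories", {
  spec <- grid_spec(c(0, 0, 0), extent = 8, spacing = 1)
  prot <- toy_structure(rbind(c(3, 0, 0), c(0, 3.2, 0)), c("C", "N"),
                        c("protein.C.aliphatic", "protein.N.donor"),
                        role = "protein")
  lig <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)), c("C", "O"),
                       c("ligand.C.aliphatic", "ligand.O.acceptor"))
  pstack <- rasterize(prot, spec)
  lstack <- rasterize(lig, spec)
  occ <- encode_hydration_channels(scalar_grid(spec, 1), "occupancy")
  stack <- assemble_input(pstack, lstack, occ, mode = "occupancy")

  # all relevance on ligand channels -> ligand fraction 1
  m <- list(input_relevance = array(0, dim = dim(stack$data)),
            channel_names = stack$channel_names, spec = spec,
            start_relevance = 1, layer_sums = 1, dropped = 0)
  class(m) <- "relevance_map"
  ch <- match("ligand.C.aliphatic", stack$channel_names)
  m$input_relevance[ch, , , ] <- stack$data[ch, , , ]
  s <- aggregate_relevance(m, prot, lig)
  expect_equal(unname(s$fractions["ligand"]), 1.0)
  expect_equal(sum(s$fractions), 1.0, tolerance = 1e-9)

  # a water voxel 1 A from a ligand atom is category "replaced"
  m2 <- m
  m2$input_relevance[] <- 0
  wch <- match("water.occupancy", stack$channel_names)
  vc <- voxel_centers(spec)
  near <- which.min(rowSums(sweep(vc, 2, c(1.0, 0, 0))^2))
  idx3 <- arrayInd(near, rep(spec$dims, 3))
  m2$input_relevance[wch, idx3[1], idx3[2], idx3[3]] <- 1
  s2 <- aggregate_relevance(m2, prot, lig)
  expect_equal(unname(s2$water_category_relevance["replaced"]), 1)
  expect_equal(unname(s2$fractions["replaced"]), 1)

  # random maps normalize to fractions summing to 1
  m3 <- m
  set.seed(15)
  m3$input_relevance <- array(abs(rnorm(length(m$input_relevance))),
                              dim = dim(m$input_relevance))
  s3 <- aggregate_relevance(m3, prot, lig)
  expect_equal(sum(s3$fractions), 1.0, tolerance = 1e-9)
  expect_true(all(s3$fractions >= 0))
})
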