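test_that("occupancy accumulation counts voxel visits against bulk", {
  spec <- grid_spec(c(0, 0, 0), extent = 4, spacing = 1)
  vc <- voxel_centers(spec)
  ctr <- vc[11, ]
  traj <- water_trajectory(frame = 1:100, water_id = rep(1L, 100),
                          coords = matrix(rep(ctr, 100), ncol = 3, byrow = TRUE),
                          energy = rep(-10, 100))
  bulk <- structure(list(bulk_occupancy = 0.2, bulk_energy = -10),
                    class = "bulk_reference")
  occ <- accumulate_occupancy(traj, spec, bulk)
  expect_equal(occ$values[arrayInd(11, rep(4, 3))], 1 / 0.2)  # counting oracle
  expect_equal(sum(occ$values > 0), 1)
  # exact count conservation: sum(ratio * bulk * n_frames) = total visits
  expect_equal(sum(occ$values) * 0.2 * 100, 100)
})

test_that("uniform bulk water gives occupancy ratio 1 within binomial error", {
  spec <- grid_spec(c(0, 0, 0), extent = 6, spacing = 1)
  sp <- synthetic_spec(n_systems = 1, n_frames = 1000, seed = 77)
  traj <- generate_water_trajectory(sp, spec)
  bulk <- bulk_reference(density = sp$bulk_density, spacing = 1,
                         energy = sp$bulk_energy)
  occ <- accumulate_occupancy(traj, spec, bulk)
  n_total <- length(traj$frame)
  # the generator rounds the per-frame count to an integer; the expected
  # mean ratio reflects that rounding exactly
  expected <- n_total / (1000 * bulk$bulk_occupancy * spec$dims^3)
  p <- 1 / spec$dims^3
  se <- sqrt(n_total * p * (1 - p)) / (1000 * bulk$bulk_occupancy)
  expect_equal(mean(occ$values), expected, tolerance = 1e-12)
  expect_lt(abs(expected - 1), 0.05)
  expect_true(all(abs(occ$values - expected) < 6 * se))
})

test_that("pseudo-site detection uses the strict twice-bulk rule", {
  spec <- grid_spec(c(0, 0, 0), extent = 4, spacing = 1)
  bulk <- structure(list(bulk_occupancy = 0.1, bulk_energy = -10),
                    class = "bulk_reference")
  traj <- water_trajectory(1, 1L, matrix(c(10, 10, 10), 1), -10)
  flat <- scalar_grid(spec, array(1, dim = rep(4, 3)))
  expect_equal(nrow(detect_pseudo_sites(flat, traj, bulk)), 0)
  # a voxel at exactly 2.0 is not a site; strictly above is
  v <- array(1, dim = rep(4, 3)); v[2, 2, 2] <- 2.0
  expect_equal(nrow(detect_pseudo_sites(scalar_grid(spec, v), traj, bulk)), 0)
  v[2, 2, 2] <- 5.0
  # place the single trajectory water at that voxel center so it contributes
  vc <- voxel_centers(spec)
  ctr <- vc[2 + 4 * 1 + 16 * 1, ]
  traj <- water_trajectory(1, 1L, matrix(ctr, 1), -12)
  sites <- detect_pseudo_sites(scalar_grid(spec, v), traj, bulk)
  expect_equal(nrow(sites), 1)
  expect_equal(unlist(sites[1, c("ix", "iy", "iz")], use.names = FALSE),
               c(2L, 2L, 2L))
  expect_equal(sites$n_contributing, 1L)
})

test_that("site thermodynamics: mean-minus-bulk enthalpy and KL entropy", {
  spec <- grid_spec(c(0, 0, 0), extent = 4, spacing = 1)
  bulk <- structure(list(bulk_occupancy = 0.01, bulk_energy = -10.0),
                    class = "bulk_reference")
  vc <- voxel_centers(spec)
  ctr <- vc[22, ]
  n <- 50
  traj <- water_trajectory(1:n, rep(1L, n),
                           matrix(rep(ctr, n), ncol = 3, byrow = TRUE),
                           energy = rep(-12, n))
  occ <- accumulate_occupancy(traj, spec, bulk)
  sites <- detect_pseudo_sites(occ, traj, bulk)
  th <- site_thermodynamics(traj, sites, bulk, temperature = 300)
  expect_equal(th$dH[1], -2.0)  # mean(-12) - (-10)
  # all contributors in one sub-bin of m total: -TdS = T k ln m
  m <- sum(rowSums(as.matrix(expand.grid(
    -1 + (1:8 - 0.5) * 0.25, -1 + (1:8 - 0.5) * 0.25,
    -1 + (1:8 - 0.5) * 0.25))^2) <= 1)
  expect_equal(th$minus_TdS[1], 300 * 0.0019872 * log(m))
})

test_that("uniformly spread contributors carry zero translational entropy", {
  spec <- grid_spec(c(0, 0, 0), extent = 4, spacing = 1)
  bulk <- structure(list(bulk_occupancy = 1e-6, bulk_energy = 0),
                    class = "bulk_reference")
  vc <- voxel_centers(spec)
  ctr <- vc[22, ]
  # one observation at the center of every sub-bin of the site sphere
  nsb <- 8
  ax <- -1 + (seq_len(nsb) - 0.5) * 0.25
  cent <- as.matrix(expand.grid(ax, ax, ax))
  cent <- cent[rowSums(cent^2) <= 1, ]
  coords <- sweep(cent, 2, ctr, "+")
  traj <- water_trajectory(seq_len(nrow(coords)), rep(1L, nrow(coords)),
                           coords, rep(-5, nrow(coords)))
  occ <- accumulate_occupancy(traj, spec, bulk)
  sites <- detect_pseudo_sites(occ, traj, bulk)
  th <- site_thermodynamics(traj, sites, bulk)
  k <- which(th$ix == 2 & th$iy == 2 & th$iz == 2)
  expect_equal(th$minus_TdS[k], 0, tolerance = 1e-12)
  expect_error(
    site_thermodynamics(traj, within(sites, contributors[1] <- list(integer(0))),
                        bulk), "no contributing")
})

test_that("QT clustering finds blob peaks with 2 A exclusion", {
  spec <- grid_spec(c(0, 0, 0), extent = 12, spacing = 0.5)
  vc <- voxel_centers(spec)
  c1 <- c(-3, 0, 0); c2 <- c(3, 0, 0)
  v <- 8 * exp(-rowSums(sweep(vc, 2, c1)^2) / (2 * 0.7^2)) +
       6 * exp(-rowSums(sweep(vc, 2, c2)^2) / (2 * 0.7^2))
  occ <- scalar_grid(spec, array(v, dim = rep(spec$dims, 3)))
  sites <- cluster_hydration_sites(occ)
  expect_equal(nrow(sites), 2)
  # brute-force argmax oracle: first site at global argmax voxel
  expect_equal(unlist(sites[1, c("x", "y", "z")], use.names = FALSE),
               vc[which.max(v), ])
  expect_lt(max(abs(unlist(sites[2, c("x", "y", "z")]) - c2)), 0.5 + 1e-9)
  expect_true(all(dist(as.matrix(sites[, c("x", "y", "z")])) >= 2.0))
  expect_true(all(diff(sites$peak_occupancy) <= 0))

  expect_equal(nrow(cluster_hydration_sites(
    scalar_grid(spec, array(1, dim = rep(spec$dims, 3))))), 0)
})

test_that("hydration channels are tanh-scaled and sign-split", {
  spec <- grid_spec(c(0, 0, 0), extent = 4, spacing = 1)
  mk <- function(dh, ts) structure(list(
    occupancy = scalar_grid(spec, 1),
    enthalpy = scalar_grid(spec, array(dh, dim = rep(4, 3))),
    entropy_term = scalar_grid(spec, array(ts, dim = rep(4, 3))),
    sites = NULL), class = "hydration_thermo_grids")
  ch0 <- encode_hydration_channels(mk(0, 0), "thermo")
  expect_true(all(ch0$data[1:2, , , ] == 0))
  ch <- encode_hydration_channels(mk(-1.5, 0.8), "thermo", s_H = 1, s_S = 1)
  expect_equal(ch$data[1, 1, 1, 1], tanh(1.5))
  expect_equal(ch$data[2, 1, 1, 1], 0)
  expect_equal(ch$data[3, 1, 1, 1], tanh(0.8))
  chp <- encode_hydration_channels(mk(2.5, 0), "thermo")
  expect_equal(chp$data[1, 1, 1, 1], 0)
  expect_equal(chp$data[2, 1, 1, 1], tanh(2.5))
  expect_true(all(ch$data >= 0 & ch$data < 1))
  # monotone: larger |dH| never yields a smaller channel value
  dhs <- seq(0, 6, by = 0.5)
  vals <- vapply(dhs, function(d)
    encode_hydration_channels(mk(-d, 0), "thermo")$data[1, 1, 1, 1], numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("overlap coefficient matches its hand evaluation and bounds", {
  expect_equal(overlap_coefficient(c(1, 1, 0), c(0, 1, 1)), 0.5)
  expect_equal(overlap_coefficient(c(2, 3, 1), c(2, 3, 1)), 1.0)
  expect_equal(overlap_coefficient(c(1, 0, 0), c(0, 0, 2)), 0.0)
  expect_error(overlap_coefficient(c(1, -1, 0), c(1, 1, 0)), "non-negative")
  expect_error(overlap_coefficient(c(0, 0, 0), c(1, 1, 0)), "positive total")
  set.seed(5)
  for (k in 1:50) {
    a <- runif(20); b <- runif(20) * rbinom(20, 1, 0.7)
    if (sum(b) == 0) b[1] <- 1
    oc <- overlap_coefficient(a, b)
    expect_gte(oc, 0); expect_lte(oc, 1 + 1e-12)
    expect_equal(oc, overlap_coefficient(b, a))
    expect_equal(oc, overlap_coefficient(3.7 * a, b))
  }
})

test_that("trajectory text round trip (multi-frame PDB + energy TSV)", {
  tdir <- tempdir()
  traj_path <- file.path(tdir, "traj.pdb")
  en_path <- file.path(tdir, "energies.tsv")
  lines <- c()
  for (f in 1:3) {
    lines <- c(lines, sprintf("MODEL %5d", f),
      sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
              1:2, 1:2, c(1.0, 2.5) + f * 0.1, c(0, 1), c(0, -1)),
      "ENDMDL")
  }
  writeLines(lines, traj_path)
  writeLines(c("# ww_halved: true", "frame\twater_id\tenergy_kcal",
               sprintf("%d\t%d\t%.2f", rep(1:3, each = 2), rep(1:2, 3),
                       -10 - (1:6) * 0.1)), en_path)
  traj <- read_water_trajectory(traj_path, en_path)
  expect_equal(traj$n_frames, 3)
  expect_equal(length(traj$frame), 6)
  expect_equal(traj$energy[traj$frame == 2 & traj$water_id == 1], -10.3)

  # ww_halved false requires and applies the ww_energy correction
  writeLines(c("# ww_halved: false", "frame\twater_id\tenergy_kcal\tww_energy",
               sprintf("%d\t%d\t%.2f\t%.2f", rep(1:3, each = 2), rep(1:2, 3),
                       -10, -4)), en_path)
  traj2 <- read_water_trajectory(traj_path, en_path)
  expect_equal(unique(traj2$energy), -10 + 2)
})
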