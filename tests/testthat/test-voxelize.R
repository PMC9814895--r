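test_that("density kernel matches its closed forms and support", {
  expect_equal(density_kernel(0, 1.7), 1.0)
  # both branch formulas agree at r = R (1/e^2)
  R <- 1.7
  gauss <- exp(-2 * R^2 / R^2)
  quad <- 4 * R^2 / (exp(2) * R^2) - 12 * R / (exp(2) * R) + 9 / exp(2)
  expect_equal(density_kernel(R, R), gauss)
  expect_equal(gauss, quad)
  expect_equal(gauss, exp(-2))
  # quadratic branch vanishes at 1.5 R: (9 - 18 + 9)/e^2
  expect_equal(density_kernel(1.5 * R, R), (9 - 18 + 9) / exp(2))
  expect_equal(density_kernel(10 * R, R), 0)
  expect_error(density_kernel(1, -1), "must be > 0")
})

test_that("density kernel is continuous at both breakpoints", {
  eps <- 1e-8
  for (R in seq(0.8, 2.4, length.out = 20)) {
    for (x0 in c(R, 1.5 * R)) {
      expect_lt(abs(density_kernel(x0 - eps, R) - density_kernel(x0 + eps, R)),
                1e-6)
    }
  }
})

test_that("rasterization sums single-atom kernels per type channel", {
  spec <- grid_spec(c(0, 0, 0), extent = 8, spacing = 0.5)
  vc <- voxel_centers(spec)
  ctr <- vc[1 + 7 + 16 * 7 + 16^2 * 7, ]  # a voxel center near the middle
  st <- toy_structure(rbind(ctr), "C", "ligand.C.aliphatic")
  stack <- rasterize(st, spec)
  ch <- get_channel(stack, "ligand.C.aliphatic")
  expect_equal(max(ch$values), 1.0)
  expect_equal(which.max(ch$values), which(apply(
    abs(sweep(vc, 2, ctr)), 1, max) < 1e-9))
  # other channels present and all-zero
  expect_equal(n_channels(stack), 18)
  expect_equal(sum(stack$data), sum(ch$values))

  # two identical atoms at the same point are additive
  st2 <- toy_structure(rbind(ctr, ctr), c("C", "C"),
                       rep("ligand.C.aliphatic", 2))
  expect_equal(max(rasterize(st2, spec)$data), 2.0)

  # empty structure -> all channels zero
  st0 <- toy_structure(matrix(numeric(0), 0, 3), character(0), character(0))
  expect_true(all(rasterize(st0, spec)$data == 0))

  # untyped heavy atom errors
  stu <- toy_structure(rbind(ctr), "C", NA_character_)
  expect_error(rasterize(stu, spec), "untyped")
})

test_that("voxelized kernel mass matches the analytic integral within 2%", {
  R <- 1.7
  analytic <- integrate(function(r) 4 * pi * r^2 * density_kernel(r, R),
                        0, 1.5 * R, rel.tol = 1e-10)$value
  spec <- grid_spec(c(0, 0, 0), extent = 12, spacing = 0.5)
  st <- toy_structure(rbind(c(0.13, -0.21, 0.08)), "C", "ligand.C.aliphatic")
  mass <- sum(rasterize(st, spec)$data) * spec$spacing^3
  expect_lt(abs(mass - analytic) / analytic, 0.02)
})

test_that("rasterization is exactly translation-equivariant", {
  shift <- c(1.23, -4.56, 0.78)
  st <- toy_structure(rbind(c(0.3, 0.1, -0.2), c(1.1, -0.4, 0.6)),
                      c("C", "O"),
                      c("ligand.C.aliphatic", "ligand.O.acceptor"))
  spec1 <- grid_spec(c(0, 0, 0), extent = 8, spacing = 0.5)
  spec2 <- grid_spec(shift, extent = 8, spacing = 0.5)
  st2 <- st
  st2$atoms$x <- st$atoms$x + shift[1]
  st2$atoms$y <- st$atoms$y + shift[2]
  st2$atoms$z <- st$atoms$z + shift[3]
  expect_equal(rasterize(st, spec1)$data, rasterize(st2, spec2)$data,
               tolerance = 1e-12)
})

test_that("augmentation is a deterministic rigid motion bounded by 2 A", {
  st <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0)),
                      c("C", "C", "N"),
                      c("ligand.C.aliphatic", "ligand.C.aliphatic",
                        "ligand.N.donor"))
  prot <- cage_structure(c(0, 0, 0), radius = 5, n = 20)
  a1 <- augment_pose(prot, st, seed = 42)
  a2 <- augment_pose(prot, st, seed = 42)
  expect_identical(a1$pose$atoms$x, a2$pose$atoms$x)
  expect_identical(a1$protein$atoms$z, a2$protein$atoms$z)
  # rigid: all pairwise distances preserved to 1e-9
  allxyz <- function(p, l) rbind(as.matrix(p$atoms[, c("x", "y", "z")]),
                                 as.matrix(l$atoms[, c("x", "y", "z")]))
  d0 <- dist(allxyz(prot, st))
  d1 <- dist(allxyz(a1$protein, a1$pose))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("augmentation draws match uniform-rotation statistics", {
  angles <- numeric(500)
  trans <- numeric(500)
  for (k in 1:500) {
    a <- augment_pose(cage_structure(c(0, 0, 0), n = 4),
                      toy_structure(rbind(c(1, 0, 0)), "C", "ligand.C.aliphatic"),
                      seed = k)
    angles[k] <- acos(pmin(1, pmax(-1, (sum(diag(a$rotation)) - 1) / 2)))
    trans[k] <- sqrt(sum(a$translation^2))
  }
  expect_lte(max(trans), 2.0)
  # closed-form mean rotation angle under uniform SO(3): pi/2 + 2/pi
  expect_lt(abs(mean(angles) - (pi / 2 + 2 / pi)) / (pi / 2 + 2 / pi), 0.05)
})

test_that("assembled inputs have 34 / 35 / 37 channels in fixed order", {
  spec <- grid_spec(c(0, 0, 0), extent = 8, spacing = 1)
  prot <- rasterize(cage_structure(c(0, 0, 0), radius = 3, n = 10), spec)
  lig <- rasterize(toy_structure(rbind(c(0, 0, 0)), "C", "ligand.C.aliphatic"),
                   spec)
  occ1 <- encode_hydration_channels(scalar_grid(spec, 1), mode = "occupancy")
  s34 <- assemble_input(prot, lig, mode = "PL")
  s35 <- assemble_input(prot, lig, hydration = occ1, mode = "occupancy")
  expect_equal(n_channels(s34), 34)
  expect_equal(n_channels(s35), 35)
  expect_equal(s35$channel_names[1:16], atom_type_vocabulary("protein"))
  expect_equal(s35$channel_names[17:34], atom_type_vocabulary("ligand"))
  expect_equal(s35$channel_names[35], "water.occupancy")

  thermo <- structure(list(
    occupancy = scalar_grid(spec, 1),
    enthalpy = scalar_grid(spec, 0),
    entropy_term = scalar_grid(spec, 0),
    sites = NULL), class = "hydration_thermo_grids")
  s37 <- assemble_input(prot, lig,
                        hydration = encode_hydration_channels(thermo, "thermo"),
                        mode = "thermo")
  expect_equal(n_channels(s37), 37)

  pr <- probe_channels(data.frame(x = 0, y = 0, z = 0, magnitude = 10,
                                  probe_sign = 1, target = "ligand"), spec)
  expect_equal(n_channels(assemble_input(prot, lig, hydration = occ1,
                                         probes = pr, mode = "occupancy")), 39)

  spec2 <- grid_spec(c(5, 5, 5), extent = 8, spacing = 1)
  lig2 <- rasterize(toy_structure(rbind(c(5, 5, 5)), "C", "ligand.C.aliphatic"),
                    spec2)
  expect_error(assemble_input(prot, lig2, mode = "PL"), "grid_spec")
  expect_error(assemble_input(prot, lig, mode = "occupancy"), "requires hydration")
})
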