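test_that("docking-frame RMSD matches hand computations", {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(4.5, 0, 0))
  bonds <- data.frame(i = 1:3, j = 2:4, order = 1, in_ring = FALSE)
  ref <- toy_structure(xyz, c("C", "N", "C", "O"),
                       c("ligand.C.aliphatic", "ligand.N.donor",
                         "ligand.C.aliphatic", "ligand.O.acceptor"), bonds)
  expect_equal(pose_rmsd(ref, ref), 0.0)
  # two atoms displaced by 2 A, two exact: sqrt((4+4)/4) = sqrt(2)
  moved <- ref
  moved$atoms$y[3:4] <- moved$atoms$y[3:4] + 2
  expect_equal(pose_rmsd(moved, ref, use_symmetry = FALSE), sqrt(2))
  # minimum over multiple references
  expect_equal(pose_rmsd(moved, list(ref, moved)), 0.0)
  # composition mismatch errors
  other <- toy_structure(xyz[1:3, ], c("C", "N", "C"),
                         rep("ligand.C.aliphatic", 3))
  expect_error(pose_rmsd(other, ref), "composition")
})

test_that("symmetry-aware RMSD nulls ring relabelings", {
  ref <- benzene_like(0)
  rot <- benzene_like(2 * pi / 6)  # rotated by one ring position
  expect_gt(pose_rmsd(rot, ref, use_symmetry = FALSE), 1.0)
  expect_equal(pose_rmsd(rot, ref, use_symmetry = TRUE), 0.0, tolerance = 1e-9)
})

test_that("symmetry RMSD never exceeds plain RMSD (random rigid motions)", {
  set.seed(31)
  for (k in 1:40) {
    ref <- benzene_like(0)
    ang <- runif(1, 0, 2 * pi)
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    pose <- ref
    xyz <- as.matrix(ref$atoms[, c("x", "y", "z")]) %*% t(Rm) +
      matrix(runif(3, -1, 1), 6, 3, byrow = TRUE)
    pose$atoms$x <- xyz[, 1]; pose$atoms$y <- xyz[, 2]; pose$atoms$z <- xyz[, 3]
    expect_lte(pose_rmsd(pose, ref, use_symmetry = TRUE),
               pose_rmsd(pose, ref, use_symmetry = FALSE) + 1e-12)
  }
})

test_that("fragment decomposition cuts acyclic single bonds between non-terminal atoms", {
  # biphenyl-like: two rings joined by one single bond -> 2 fragments
  r1 <- benzene_like(0)
  r2 <- benzene_like(0)
  r2$atoms$x <- r2$atoms$x + 4
  atoms <- rbind(r1$atoms, r2$atoms)
  atoms$index <- seq_len(nrow(atoms))
  bonds <- rbind(r1$bonds,
                 within(r2$bonds, { i <- i + 6; j <- j + 6 }),
                 data.frame(i = 1, j = 7, order = 1, in_ring = FALSE))
  biphenyl <- hydrascore:::new_structure(atoms, bonds, role = "ligand")
  frags <- fragment_decompose(biphenyl)
  expect_length(frags, 2)
  expect_equal(sort(lengths(frags)), c(6, 6))
  # a single rigid ring stays one fragment
  expect_length(fragment_decompose(benzene_like(0)), 1)
  # ethane-like 2 heavy atoms: terminal bond is not cut
  eth <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)), c("C", "C"),
                       rep("ligand.C.aliphatic", 2),
                       data.frame(i = 1, j = 2, order = 1, in_ring = FALSE))
  expect_length(fragment_decompose(eth), 1)
})

test_that("Shrake-Rupley SASA matches the closed-form sphere and occlusion", {
  iso <- toy_structure(rbind(c(0, 0, 0)), "C", "ligand.C.aliphatic")
  s <- shrake_rupley_sasa(iso)
  expect_lt(abs(s[1] - 4 * pi * (1.7 + 1.4)^2) / (4 * pi * (1.7 + 1.4)^2), 0.01)
  # deterministic
  expect_identical(s, shrake_rupley_sasa(iso))
  # fully buried atom has ~zero SASA
  cage <- cage_structure(c(0, 0, 0), radius = 2.0, n = 200)
  expect_lt(shrake_rupley_sasa(iso, context = cage)[1], 1e-6)
  # occlusion strictly reduces area for a bonded diatomic
  dia <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)), c("C", "C"),
                       rep("ligand.C.aliphatic", 2))
  expect_lt(sum(shrake_rupley_sasa(dia)), 2 * s[1])
})

test_that("modified RMSD ignores solvent-exposed fragments", {
  # chain A-B-C-D: fragment {A,B} buried in a cage, {C,D} exposed
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0), c(4.5, 0, 0))
  bonds <- data.frame(i = 1:3, j = 2:4, order = 1, in_ring = FALSE)
  ref <- toy_structure(xyz, rep("C", 4), rep("ligand.C.aliphatic", 4), bonds)
  cage <- cage_structure(c(0.75, 0, 0), radius = 2.6, n = 250)
  pose <- ref
  pose$atoms$y[3:4] <- pose$atoms$y[3:4] + 2
  res <- modified_rmsd(pose, ref, cage)
  expect_equal(res$standard_rmsd, sqrt(2))
  expect_equal(res$modified_rmsd, 0.0)
  expect_equal(res$excluded, c(FALSE, TRUE))
  expect_true(all(res$ratio >= 0))
  # identical pose: zero regardless of exclusions
  expect_equal(modified_rmsd(ref, ref, cage)$modified_rmsd, 0.0)
  # fully exposed ligand falls back to the standard RMSD with a warning
  far <- ref
  far$atoms$x <- far$atoms$x + 50
  posef <- far; posef$atoms$y <- posef$atoms$y + 1
  expect_warning(resf <- modified_rmsd(posef, far, cage), "exposed")
  expect_equal(resf$modified_rmsd, resf$standard_rmsd)
})

test_that("contact mode score is a Tanimoto over contact sets", {
  prot <- toy_structure(rbind(c(0, 0, 3)), "C", "protein.C.aliphatic",
                        role = "protein")
  ref <- toy_structure(rbind(c(0, 0, 0), c(20, 0, 0)), c("C", "O"),
                       c("ligand.C.aliphatic", "ligand.O.acceptor"))
  expect_equal(contact_mode_score(ref, ref, prot), 1.0)
  # pose adds a second contact: {(p1,l1),(p1,l2)} vs {(p1,l1)} -> 0.5
  pose <- ref
  pose$atoms$x[2] <- 1.5
  expect_equal(contact_mode_score(pose, ref, prot), 0.5)
  expect_equal(contact_mode_score(ref, pose, prot), 0.5)  # symmetric
  # disjoint contact sets -> 0
  pose2 <- ref
  pose2$atoms$z <- pose2$atoms$z - 30
  expect_equal(contact_mode_score(pose2, ref, prot), 0.0)
  # both empty -> defined as 1
  farp <- prot; farp$atoms$z <- 1000
  expect_equal(contact_mode_score(pose2, ref, farp), 1.0)
})

test_that("pose labeling uses a strict 2 A threshold", {
  expect_true(label_pose(1.9))
  expect_false(label_pose(2.0))
  expect_false(label_pose(7.3))
  expect_equal(label_pose(c(0.5, 2.0, 1.999)), c(TRUE, FALSE, TRUE))
})

test_that("fold splitting groups linked systems and balances greedily", {
  n <- 6
  sd_ <- matrix(1, n, n); diag(sd_) <- 0
  ls_ <- matrix(0, n, n)
  # links: A-B (sequence), C-D (ligand)
  sd_[1, 2] <- sd_[2, 1] <- 0.2
  ls_[3, 4] <- ls_[4, 3] <- 0.95
  out <- split_folds(sd_, ls_, n_folds = 3)
  expect_equal(sort(out$fold_sizes), c(2, 2, 2))
  expect_equal(out$fold[1], out$fold[2])
  expect_equal(out$fold[3], out$fold[4])
  expect_length(out$groups, 4)

  # all dissimilar, 9 systems -> 3/3/3 round robin
  sd9 <- matrix(1, 9, 9); diag(sd9) <- 0
  out9 <- split_folds(sd9, matrix(0, 9, 9), n_folds = 3)
  expect_equal(out9$fold_sizes, c(3L, 3L, 3L))

  # one group of 5 in a 6-system set -> (5, 1, 0), reported
  sd6 <- matrix(1, 6, 6); diag(sd6) <- 0
  sd6[1:5, 1:5] <- 0.1
  expect_message(out6 <- split_folds(sd6, matrix(0, 6, 6), n_folds = 3),
                 "imbalance")
  expect_equal(sort(out6$fold_sizes, decreasing = TRUE), c(5L, 1L, 0L))

  expect_error(split_folds(matrix(0, 2, 2), matrix(0, 3, 3)), "square")
})

test_that("no linked pair is ever split across folds (random matrices)", {
  set.seed(41)
  for (k in 1:20) {
    n <- sample(8:16, 1)
    sd_ <- matrix(runif(n * n, 0.3, 1), n, n); sd_ <- (sd_ + t(sd_)) / 2
    diag(sd_) <- 0
    ls_ <- matrix(runif(n * n, 0.5, 1), n, n); ls_ <- (ls_ + t(ls_)) / 2
    diag(ls_) <- 1
    out <- suppressMessages(split_folds(sd_, ls_, n_folds = 3))
    link <- (sd_ < 0.5 | ls_ > 0.9); diag(link) <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) if (link[i, j])
      expect_equal(out$fold[i], out$fold[j])
    expect_lte(max(out$fold_sizes) - min(out$fold_sizes),
               max(lengths(out$groups)))
  }
})
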