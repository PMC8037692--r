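test_that("identity extremes: identical 100, fully different 0, symmetric", {
  expect_equal(pairwise_identity("MKTAYIAKQR", "MKTAYIAKQR"), 100)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  a <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  b <- "MKTAYIAKQRQISFVKSHFSRQLGERLELIEVQ"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_error(pairwise_identity("MKT1", "MKT"), "non-amino-acid")
  expect_error(pairwise_identity("", "MKT"), "empty")
})

test_that("planted sequence divergence is recovered exactly", {
  for (seed in 1:5) {
    hp <- gen_homolog_sequences(160, identity = 0.87, seed = seed)
    got <- pairwise_identity(hp$a, hp$b)
    expect_equal(got, 100 * hp$planted_identity, tolerance = 1e-9)
  }
  # a different planted level is recovered too
  hp2 <- gen_homolog_sequences(200, identity = 0.95, seed = 7)
  expect_equal(pairwise_identity(hp2$a, hp2$b), 100 * hp2$planted_identity,
               tolerance = 1e-9)
})

test_that("superposition: self is zero, a rigid rotation is undone", {
  sa <- gen_toy_structure(20)
  expect_equal(superpose(sa, sa)$rmsd, 0, tolerance = 1e-9)
  sb <- sa
  xyz <- as.matrix(sb$atoms[, c("x", "y", "z")])
  xyz <- rotate_about_axis(xyz, c(0, 0, 0), c(1, 1, 1), 1.1)
  sb$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -3, 2), "+")
  expect_equal(superpose(sa, sb, "all")$rmsd, 0, tolerance = 1e-9)
  # superposed rmsd never exceeds the in-place deviation
  raw <- sqrt(mean(rowSums((as.matrix(sb$atoms[, c("x", "y", "z")]) -
                              as.matrix(sa$atoms[, c("x", "y", "z")]))^2)))
  expect_lte(superpose(sa, sb, "all")$rmsd, raw)
})

test_that("Kabsch agrees with the quaternion closed form on noisy point sets", {
  set.seed(21)
  for (case in 1:20) {
    n <- sample(4:12, 1)
    A <- matrix(rnorm(3 * n, sd = 3), n, 3)
    B <- rotate_about_axis(A, c(0, 0, 0), rnorm(3), runif(1, -pi, pi)) +
      matrix(rnorm(3 * n, sd = 0.2), n, 3)
    expect_equal(kabsch(A, B)$rmsd, oracle_superpose_rmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("deviation profiles are zero on self and spike at displaced residues", {
  sa <- gen_toy_structure(20)
  prof_self <- ensemble_rmsd_profile(list(sa), sa, "ca")
  expect_lt(max(prof_self), 1e-9)
  sb <- gen_toy_structure(20, displace = list(resno = 10, by = c(2, 0, 0)))
  sc <- gen_toy_structure(20, displace = list(resno = 15, by = c(0, 3, 0)))
  prof <- ensemble_rmsd_profile(list(sb, sc), sa, "ca")
  expect_equal(rownames(prof)[which.max(prof[, 1])], "10")
  expect_equal(rownames(prof)[which.max(prof[, 2])], "15")
  # away from the perturbed residue the deviations stay comparatively small
  expect_gt(prof["10", 1], 3 * stats::median(prof[-10, 1]))
})

test_that("structure models read from PDB text round-trip residue content", {
  tr <- gen_trajectory(n_frames = 2, n_waters = 3, ligand = "none",
                       n_inside = 0, seed = 5)
  path <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, path)
  sm <- read_structure(path, chain = "A")
  expect_equal(length(sm$resnos), 20)
  expect_equal(nchar(sm$sequence), 20)
  expect_true(all(sm$atoms$element %in% c("N", "C", "O")))
})
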