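test_that("substructure RMSD: identity is zero, translation is analytic", {
  ref <- fix_ref_ligand()
  expect_equal(substructure_rmsd(ref, ref, thq_pattern())$rmsd, 0,
               tolerance = 1e-12)
  for (d in c(0.5, 2, 4.25)) {
    moved <- ref
    moved$xyz <- sweep(moved$xyz, 2, c(d, 0, 0), "+")
    expect_equal(substructure_rmsd(moved, ref, thq_pattern())$rmsd, d,
                 tolerance = 1e-9)
  }
})

test_that("symmetric patterns take the minimum over automorphic mappings", {
  # benzene ring pattern has 12 automorphisms; rotate toluene's ring by one
  # position and the anchored RMSD must use the automorphism, not the
  # identity mapping
  tol <- embed_3d("Cc1ccccc1")
  ring_pat <- mol_graph("c1ccccc1")
  pose <- tol
  pose$xyz <- sweep(pose$xyz, 2, c(0.3, 0, 0), "+")
  prod_rmsd <- substructure_rmsd(pose, tol, ring_pat)$rmsd
  pat_mol <- quick_mol(rep("C", 6), matrix(0, 6, 3),
                       data.frame(a1 = 1:6, a2 = c(2:6, 1),
                                  order = c(2, 1, 2, 1, 2, 1)))
  oracle <- oracle_min_rmsd(pose, tol, pat_mol)
  expect_equal(prod_rmsd, oracle, tolerance = 1e-9)
})

test_that("production minimum equals the brute-force mapping oracle on random cases", {
  ref <- fix_ref_ligand()
  thq_mol <- quick_mol(
    c("N", rep("C", 9)), matrix(0, 10, 3),
    data.frame(a1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 9, 10),
               a2 = c(2, 3, 4, 5, 6, 7, 8, 9, 4, 10, 1),
               order = c(1, 1, 1, 2, 1, 2, 1, 2, 1, 1, 1)))
  set.seed(11)
  for (case in 1:25) {
    pose <- ref
    # random rigid move + mild per-atom noise
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    pose$xyz <- rotate_about_axis(pose$xyz, colMeans(pose$xyz),
                                  colMeans(pose$xyz) + axis,
                                  runif(1, -pi, pi))
    pose$xyz <- sweep(pose$xyz, 2, rnorm(3, sd = 2), "+") +
      matrix(rnorm(length(pose$xyz), sd = 0.05), nrow(pose$xyz), 3)
    got <- substructure_rmsd(pose, ref, thq_pattern())$rmsd
    want <- oracle_min_rmsd(pose, ref, thq_mol)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("substructure RMSD is symmetric and errors name the offending side", {
  ref <- fix_ref_ligand()
  pose <- ref
  pose$xyz <- pose$xyz + matrix(rnorm(length(pose$xyz), sd = 0.3),
                                nrow(pose$xyz), 3)
  expect_equal(substructure_rmsd(pose, ref, thq_pattern())$rmsd,
               substructure_rmsd(ref, pose, thq_pattern())$rmsd,
               tolerance = 1e-9)
  benz <- embed_3d("c1ccccc1")
  expect_error(substructure_rmsd(benz, ref, thq_pattern()), "pose structure")
  expect_error(substructure_rmsd(ref, benz, thq_pattern()),
               "reference structure")
})

test_that("redocking validation succeeds iff a pose reproduces the crystal", {
  ref <- fix_ref_ligand()
  near <- ref; near$xyz <- near$xyz + 0.5
  far1 <- ref; far1$xyz <- sweep(far1$xyz, 2, c(6, 0, 0), "+")
  far2 <- ref; far2$xyz <- sweep(far2$xyz, 2, c(0, 7, 0), "+")
  ok <- redock_validation(list(far1, ref, near), ref, threshold = 3)
  expect_true(ok$success)
  expect_equal(ok$best_rmsd, 0, tolerance = 1e-12)
  expect_equal(ok$best_pose, 2)
  bad <- redock_validation(list(far1, far2), ref, threshold = 3)
  expect_false(bad$success)
  # threshold zero only passes an exact duplicate
  expect_false(redock_validation(list(near), ref, threshold = 0)$success)
  benz <- embed_3d("c1ccccc1")
  expect_error(redock_validation(list(benz), ref), "atom-count mismatch")
})

test_that("match frequency recovers planted counts exactly and is monotone", {
  ref <- fix_ref_ligand()
  for (k in c(0L, 8L, 34L, 50L)) {
    ps <- gen_pose_set(ref, N = 50, k = k, threshold = 2, seed = 100 + k)
    mf <- match_frequency(list(ps$poses), ref, pattern = thq_pattern(),
                          threshold = 2)
    expect_equal(mf$k, k)
    expect_equal(mf$label, paste0(k, "/50"))
  }
  ps <- gen_pose_set(ref, N = 50, k = 8, threshold = 2, seed = 1)
  f1 <- match_frequency(list(ps$poses), ref, thq_pattern(), threshold = 2)
  f2 <- match_frequency(list(ps$poses), ref, thq_pattern(), threshold = 3.2)
  f3 <- match_frequency(list(ps$poses), ref, thq_pattern(), threshold = 1e6)
  expect_lte(f1$k, f2$k)
  expect_equal(f3$label, "50/50")
  expect_error(match_frequency(list(), ref), "empty")
})

test_that("pocket selectivity ranks by best score and flags dethroned targets", {
  scores <- data.frame(pocket = rep(c("thq", "p2", "p3"), each = 3),
                       score = c(60, 55, 52, 48, 44, 40, 51, 50, 30))
  sel <- pocket_selectivity(scores, "thq", "higher_better")
  expect_equal(sel$target_rank, 1)
  expect_false(sel$flagged)
  sel2 <- pocket_selectivity(scores, "p2", "higher_better")
  expect_true(sel2$flagged)
  # lower-is-better convention flips the ranking: p3 (best 30) wins
  sel3 <- pocket_selectivity(scores, "p3", "lower_better")
  expect_false(sel3$flagged)
  expect_true(pocket_selectivity(scores, "thq", "lower_better")$flagged)
  # a tie at the top counts as similar affinity, no flag
  tied <- data.frame(pocket = c("thq", "p2"), score = c(50, 50))
  expect_false(pocket_selectivity(tied, "thq", "higher_better")$flagged)
  expect_false(pocket_selectivity(tied, "p2", "higher_better")$flagged)
  expect_error(pocket_selectivity(scores, "nope", "higher_better"), "absent")
})

test_that("pose clustering separates bundles and picks best-scored representatives", {
  ref <- fix_ref_ligand()
  bundle1 <- lapply(1:3, function(i) {
    m <- ref; m$xyz <- m$xyz + 0.05 * i; m
  })
  bundle2 <- lapply(1:3, function(i) {
    m <- ref; m$xyz <- sweep(m$xyz, 2, c(10, 0, 0), "+") + 0.05 * i; m
  })
  poses <- c(bundle1, bundle2)
  scores <- c(40, 60, 50, 45, 30, 55)
  cl <- cluster_poses(poses, scores, cutoff = 2)
  expect_equal(cl$n_clusters, 2)
  expect_equal(cl$clusters[1:3], rep(cl$clusters[1], 3))
  expect_equal(cl$clusters[4:6], rep(cl$clusters[4], 3))
  expect_setequal(cl$representatives, c(2, 6))   # best score per bundle
  same <- cluster_poses(list(ref, ref, ref), cutoff = 1)
  expect_equal(same$n_clusters, 1)
  tiny <- cluster_poses(bundle1, cutoff = 1e-9)
  expect_equal(tiny$n_clusters, 3)   # cutoff ~ 0: singletons
  expect_error(cluster_poses(list(ref)), "two poses")
})

test_that("score tables demand an explicit convention", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# convention: higher_better",
               "ligand,receptor,pocket,pose_index,score",
               "can1,h,thq,1,62.1"), path)
  df <- read_score_table(path)
  expect_equal(attr(df, "convention"), "higher_better")
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("ligand,receptor,pocket,pose_index,score",
               "can1,h,thq,1,62.1"), path2)
  expect_error(read_score_table(path2), "convention")
  expect_equal(attr(read_score_table(path2, "lower_better"), "convention"),
               "lower_better")
})
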