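test_that("RMSD series: static and rigidly rotated trajectories are zero", {
  tr <- gen_trajectory(n_frames = 5, n_waters = 0, n_inside = 0,
                       ligand = "none", seed = 1)
  expect_equal(rmsd_series(tr), rep(0, 5), tolerance = 1e-9)
  rot <- tr
  rot$frames <- lapply(seq_along(rot$frames), function(i) {
    rotate_about_axis(rot$frames[[i]], c(20, 20, 20), c(21, 20, 20),
                      0.3 * i)
  })
  expect_equal(rmsd_series(rot), rep(0, 5), tolerance = 1e-9)
})

test_that("a single displaced atom contributes d/sqrt(n) without refitting", {
  n <- 10
  top <- data.frame(element = "C", name = "CA", resno = 1:n, resid = "ALA",
                    segment = "protein", water_id = NA_integer_)
  base <- matrix(rnorm(3 * n, sd = 4), n, 3)
  d <- 1.7
  f2 <- base; f2[4, 1] <- f2[4, 1] + d
  tr <- trajectory(top, list(base, f2, base))
  rs <- rmsd_series(tr, selection = "ca", superpose = FALSE)
  expect_equal(rs, c(0, d / sqrt(n), 0), tolerance = 1e-9)
})

test_that("RMSF converges to sigma*sqrt(3) under isotropic jitter", {
  sigma <- 0.25
  tr <- gen_trajectory(n_frames = 2000, jitter = sigma, ligand = "none",
                       n_waters = 0, n_inside = 0, seed = 17)
  rf <- rmsf_profile(tr, selection = "backbone")
  expect_equal(mean(rf), sigma * sqrt(3), tolerance = 0.05 * sigma * sqrt(3))
})

test_that("a mobile loop elevates RMSF only at its residues", {
  tr <- gen_trajectory(n_frames = 60, jitter = 0, ligand = "none",
                       n_waters = 0, n_inside = 0, seed = 3)
  loop <- which(tr$topology$resno %in% 5:7)
  tr$frames <- with_seed(8, lapply(seq_along(tr$frames), function(i) {
    x <- tr$frames[[i]]
    x[loop, ] <- x[loop, ] + matrix(rnorm(3 * length(loop), sd = 0.8),
                                    length(loop), 3)
    x
  }))
  rf <- rmsf_profile(tr, selection = "backbone")
  expect_true(all(rf[as.character(5:7)] > 5 * max(rf[as.character(10:20)])))
})

test_that("water occupancy equals brute-force counting, wrap included", {
  box <- c(30, 30, 30)
  ctr <- c(1, 15, 15)   # near a periodic face
  set.seed(31)
  for (case in 1:20) {
    n_w <- 25
    pts <- cbind(runif(n_w, 0, 30), runif(n_w, 0, 30), runif(n_w, 0, 30))
    top <- data.frame(element = c("C", rep("O", n_w)),
                      name = c("CA", rep("OW", n_w)),
                      resno = c(1L, 100L + seq_len(n_w)),
                      resid = c("ALA", rep("HOH", n_w)),
                      segment = c("protein", rep("water", n_w)),
                      water_id = c(NA_integer_, seq_len(n_w)))
    fr <- rbind(c(15, 15, 15), pts)
    tr <- trajectory(top, list(fr), box = box)
    got <- water_occupancy(tr, ctr, radius = 6)
    # brute force over the 27 periodic images
    brute <- sum(vapply(seq_len(n_w), function(i) {
      img <- expand.grid(ix = -1:1, iy = -1:1, iz = -1:1)
      dmin <- min(sqrt(colSums((t(as.matrix(img)) * box +
                                  (pts[i, ] - ctr))^2)))
      dmin <= 6
    }, logical(1)))
    expect_equal(got, brute)
  }
})

test_that("the 6 A boundary is inclusive and planted counts are recovered", {
  top <- data.frame(element = "O", name = "OW", resno = 101:103,
                    resid = "HOH", segment = "water", water_id = 1:3)
  fr <- rbind(c(6, 0, 0), c(5.999, 0, 0), c(6.001, 0, 0))
  tr <- trajectory(top, list(fr), box = NULL)
  expect_equal(water_occupancy(tr, c(0, 0, 0), 6), 2L)
  tr2 <- gen_trajectory(n_frames = 20, n_waters = 16, n_inside = 5,
                        ligand = "none", seed = 23)
  occ <- water_occupancy(tr2, pocket_center(attr(tr2, "pocket_residues")), 6)
  expect_equal(occ, rep(5L, 20))
  tr3 <- gen_trajectory(n_frames = 4, n_waters = 0, n_inside = 0,
                        ligand = "none", seed = 2)
  expect_warning(occ0 <- water_occupancy(tr3, c(0, 0, 0), 6), "no waters")
  expect_equal(occ0, rep(0L, 4))
})

test_that("ligand residency: resident stays, planted escapes are localized", {
  tr <- gen_trajectory(n_frames = 60, ligand = "resident", n_waters = 5,
                       n_inside = 2, seed = 5)
  ctr <- pocket_center(attr(tr, "pocket_residues"))
  expect_equal(ligand_residency(tr, ctr, radius = 6)$status, "resident")
  tr2 <- gen_trajectory(n_frames = 60, ligand = "escape", escape_frame = 31,
                        n_waters = 5, n_inside = 2, seed = 5)
  res <- ligand_residency(tr2, ctr, radius = 6, persistence = 10)
  expect_equal(res$status, "departed")
  expect_gte(res$departure_frame, 31)
  expect_lte(res$departure_frame, 41)
  # a single-frame excursion is forgiven by the persistence rule
  tr3 <- tr
  lig <- which(tr3$topology$segment == "ligand")
  tr3$frames[[30]][lig, ] <- tr3$frames[[30]][lig, ] + 20
  expect_equal(ligand_residency(tr3, ctr, radius = 6,
                                persistence = 10)$status, "resident")
  tr4 <- gen_trajectory(n_frames = 5, ligand = "none", n_waters = 2,
                        n_inside = 0, seed = 1)
  expect_error(ligand_residency(tr4, ctr), "no ligand")
})

test_that("escape detection recovers the planted departure over many seeds", {
  hits <- vapply(1:40, function(s) {
    tr <- gen_trajectory(n_frames = 40, ligand = "escape", escape_frame = 20,
                         n_waters = 0, n_inside = 0, jitter = 0.05, seed = s)
    res <- ligand_residency(tr, pocket_center(attr(tr, "pocket_residues")),
                            radius = 6, persistence = 5)
    res$status == "departed" &&
      res$departure_frame >= 20 && res$departure_frame <= 25
  }, logical(1))
  expect_true(all(hits))
})
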