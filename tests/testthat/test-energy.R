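test_that("per-frame binding energy is the component sum", {
  fr <- data.frame(frame = 1:2, dE_MM = c(-50, 0), dG_polar = c(30, 0),
                   dG_nonpolar = c(-5, 0))
  expect_equal(frame_binding_energy(fr), c(-25, 0))
  expect_error(frame_binding_energy(fr[, -2]), "missing component")
  # randomized tables match an independent recomputation
  ef <- gen_energy_tables(n_frames = 50, seed = 3)
  expect_equal(frame_binding_energy(ef),
               ef$dE_MM + ef$dG_polar + ef$dG_nonpolar)
})

test_that("summaries: constant series has zero SD, component means sum to total", {
  const <- data.frame(frame = 1:10, dE_MM = -40, dG_polar = 25,
                      dG_nonpolar = -4)
  s <- summarize_energy(const)
  expect_equal(unname(s$sd["total"]), 0)
  expect_false(s$fluctuation_flag)
  ef <- gen_energy_tables(n_frames = 500, seed = 6)
  s2 <- summarize_energy(ef)
  expect_equal(unname(s2$mean["total"]),
               unname(sum(s2$mean[ENERGY_COMPONENTS])), tolerance = 1e-12)
})

test_that("injected variance is recovered and flags large fluctuations", {
  ef <- gen_energy_tables(n_frames = 4000,
                          sds = c(dE_MM = 12, dG_polar = 1,
                                  dG_nonpolar = 0.2), seed = 8)
  s <- summarize_energy(ef, fluctuation_threshold = 10)
  true_sd <- sqrt(12^2 + 1^2 + 0.2^2)
  expect_equal(unname(s$sd["total"]), true_sd, tolerance = 0.05 * true_sd)
  expect_true(s$fluctuation_flag)
  # planted means recovered within 3 sigma / sqrt(n)
  expect_equal(unname(s$mean["total"]), -19,
               tolerance = 3 * true_sd / sqrt(4000))
})

test_that("per-residue maps conserve the frame totals and classify signs", {
  ef <- gen_energy_tables(n_frames = 100, residues = c(37, 41, 78, 150),
                          seed = 4)
  res_cols <- grep("^res_", names(ef), value = TRUE)
  expect_lt(max(abs(rowSums(ef[, res_cols]) - frame_binding_energy(ef))),
            1e-9)
  pm <- per_residue_map(ef)
  expect_setequal(pm$resno, c(37, 41, 78, 150))
  expect_equal(sum(pm$mean), mean(frame_binding_energy(ef)),
               tolerance = 1e-9)
  # explicit sign classification, including an unfavorable residue
  handmade <- data.frame(frame = 1:5, dE_MM = 0, dG_polar = 0,
                         dG_nonpolar = 0,
                         res_37 = 1.5, res_41 = -2.0, res_78 = 0)
  pm2 <- per_residue_map(handmade)
  expect_equal(pm2$class[pm2$resno == 37], "unfavorable")
  expect_equal(pm2$class[pm2$resno == 41], "favorable")
  expect_equal(pm2$class[pm2$resno == 78], "neutral")
  expect_equal(pm2$mean[pm2$resno == 41], -2.0)
  expect_error(per_residue_map(ef[, !grepl("res_", names(ef))]),
               "no per-residue")
})

test_that("energy tables round-trip through their CSV interchange format", {
  ef <- gen_energy_tables(n_frames = 20, residues = c(1, 2), seed = 10)
  path <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(ef), path, row.names = FALSE)
  back <- read_energy_table(path)
  expect_s3_class(back, "energy_frames")
  expect_equal(frame_binding_energy(back), frame_binding_energy(ef),
               tolerance = 1e-12)
  writeLines("frame,dE_MM\n1,2", path)
  expect_error(read_energy_table(path), "must have columns")
})
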