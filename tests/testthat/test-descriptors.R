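test_that("methane's anchor descriptors are exact", {
  dt <- compute_descriptors("C")
  expect_equal(dt$MW, 16.04, tolerance = 1e-3)
  expect_equal(dt$HBD, 0)
  expect_equal(dt$HBA, 0)
  expect_equal(dt$n_rings, 0)
  expect_false(dt$flag)
})

test_that("shape limits: a collinear rod gives (0,1), a regular hexagon (0.5,0.5)", {
  rod <- quick_mol(rep("C", 8), cbind(seq_len(8) * 1.5, 0, 0))
  sd_rod <- shape_descriptors(rod)
  expect_equal(unname(sd_rod["NPR1"]), 0, tolerance = 1e-12)
  expect_equal(unname(sd_rod["NPR2"]), 1, tolerance = 1e-12)
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  hexa <- quick_mol(rep("C", 6), cbind(1.4 * cos(ang), 1.4 * sin(ang), 0))
  sd_hex <- shape_descriptors(hexa)
  expect_equal(unname(sd_hex["NPR1"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(sd_hex["NPR2"]), 0.5, tolerance = 1e-9)
})

test_that("every generated conformer sits inside the NPR triangle", {
  cs <- fix_conformers_can125()
  for (m in cs$conformers) {
    sdm <- shape_descriptors(m)
    expect_lte(sdm["NPR1"], sdm["NPR2"] + 1e-9)
    expect_lte(sdm["NPR2"], 1 + 1e-9)
    expect_gte(sdm["NPR1"] + sdm["NPR2"], 1 - 1e-9)
  }
})

test_that("shape classification picks the nearest triangle vertex", {
  expect_equal(classify_shape(0, 1), "rod")
  expect_equal(classify_shape(1, 1), "sphere")
  expect_equal(classify_shape(0.5, 0.5), "disc")
  # (0.45, 0.62): d^2 to rod 0.3469, disc 0.0169, sphere 0.4469 -> disc
  expect_equal(classify_shape(0.45, 0.62), "disc")
  expect_error(classify_shape(0.2, 0.3), "triangle")
})

test_that("rule-of-five flags fire exactly where thresholds force them", {
  tab <- data.frame(id = c("ok", "big", "greasy"),
                    MW = c(300, 600, 420), LogP = c(2, 3, 7.2),
                    HBD = c(2, 2, 1), HBA = c(5, 5, 3),
                    TPSA = c(80, 80, 40))
  r5 <- ro5_extended(tab)
  expect_equal(r5$pass, c(TRUE, FALSE, FALSE))
  expect_equal(unname(unlist(r5$flags[2, -1])),
               c(FALSE, TRUE, TRUE, TRUE, TRUE))   # fails exactly MW
  expect_equal(unname(unlist(r5$flags[3, -1])),
               c(TRUE, FALSE, TRUE, TRUE, TRUE))   # fails exactly LogP
  expect_equal(r5$pass_rate, 1 / 3)
})

test_that("the hydroxybenzyl propanamide candidate passes the extended rule of five", {
  smi <- "OCC(N1CCc2c(C)cccc2C1)C(=O)NCc1cccc(O)c1"
  dt <- compute_descriptors(smi)
  # independent oracle: molecular formula C20H24N2O3 summed from atomic masses
  g <- mol_graph(smi)
  el <- igraph::V(g)$element
  h <- sum(implicit_hydrogens(g))
  masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999)
  mw_oracle <- sum(masses[el]) + h * masses[["H"]]
  expect_equal(dt$MW, mw_oracle, tolerance = 0.01)
  expect_equal(dt$HBD, 3)   # two hydroxyls + amide NH
  expect_equal(dt$HBA, 5)   # N2 + O3
  r5 <- ro5_extended(dt)
  expect_true(r5$pass)
})

test_that("rows with failing molecules are flagged, not dropped", {
  dt <- suppressWarnings(compute_descriptors(c("C", "totally)(broken")))
  expect_equal(nrow(dt), 2)
  expect_false(dt$flag[1])
  expect_true(dt$flag[2])
  expect_true(is.na(dt$MW[2]))
})
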