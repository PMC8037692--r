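# Interaction geometry fixtures are built atom by atom so every cutoff is
# exercised at a known distance/angle.

make_frame <- function(atoms) {
  top <- do.call(rbind, lapply(atoms, function(a) {
    data.frame(element = a$el, name = a$nm, resno = a$res,
               resid = a$resid, segment = a$seg, water_id = NA_integer_)
  }))
  xyz <- do.call(rbind, lapply(atoms, function(a) matrix(a$p, 1)))
  trajectory(top, list(xyz))
}

atomspec <- function(el, nm, res, resid, seg, p) {
  list(el = el, nm = nm, res = res, resid = resid, seg = seg, p = p)
}

test_that("an ideal O-H...O geometry is a hydrogen bond; 5 A is not", {
  near <- make_frame(list(
    atomspec("O", "O1", 900, "LIG", "ligand", c(0, 0, 0)),
    atomspec("H", "H1", 900, "LIG", "ligand", c(1.0, 0, 0)),
    atomspec("O", "O", 41, "ARG", "protein", c(2.8, 0, 0))))
  ev <- detect_interactions(near, 1)
  hb <- ev[ev$kind == "hbond", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$resno, 41)
  expect_equal(hb$distance, 2.8, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  far <- make_frame(list(
    atomspec("O", "O1", 900, "LIG", "ligand", c(0, 0, 0)),
    atomspec("H", "H1", 900, "LIG", "ligand", c(1.0, 0, 0)),
    atomspec("O", "O", 41, "ARG", "protein", c(5.0, 0, 0))))
  expect_equal(nrow(detect_interactions(far, 1)), 0)
})

test_that("a bent close contact fails the angle criterion with hydrogens present", {
  bent <- make_frame(list(
    atomspec("O", "O1", 900, "LIG", "ligand", c(0, 0, 0)),
    atomspec("H", "H1", 900, "LIG", "ligand", c(0, 1.0, 0)),   # 90 degrees
    atomspec("O", "O", 41, "ARG", "protein", c(3.0, 0, 0))))
  ev <- detect_interactions(bent, 1)
  expect_equal(sum(ev$kind == "hbond"), 0)
})

test_that("without hydrogens the heavy-atom fallback warns and still detects", {
  heavy <- make_frame(list(
    atomspec("N", "N1", 900, "LIG", "ligand", c(0, 0, 0)),
    atomspec("O", "OE1", 37, "GLU", "protein", c(3.2, 0, 0))))
  expect_warning(ev <- detect_interactions(heavy, 1), "heavy-atom")
  expect_equal(sum(ev$kind == "hbond"), 1)
})

test_that("a shared water bridges ligand and residue", {
  wb <- make_frame(list(
    atomspec("O", "O1", 900, "LIG", "ligand", c(0, 0, 0)),
    atomspec("O", "OW", 1001, "HOH", "water", c(3.0, 0, 0)),
    atomspec("O", "OE1", 37, "GLU", "protein", c(6.0, 0, 0))))
  wb$topology$water_id[2] <- 1L
  ev <- suppressWarnings(detect_interactions(wb, 1))
  expect_equal(sum(ev$kind == "water_bridge"), 1)
  expect_equal(ev$resno[ev$kind == "water_bridge"], 37)
})

test_that("pi-cation, vdw and salt-bridge cutoffs fire where constructed", {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- lapply(seq_along(ang), function(i) {
    atomspec("C", paste0("C", c("G", "D1", "D2", "E1", "E2", "Z")[i]), 74,
             "PHE", "protein", c(1.4 * cos(ang[i]), 1.4 * sin(ang[i]), 0))
  })
  fr <- make_frame(c(ring, list(
    atomspec("N", "N1", 900, "LIG", "ligand", c(0, 0, 4.0)),
    atomspec("C", "C1", 900, "LIG", "ligand", c(3.0, 0, 1.5)),
    atomspec("O", "OD1", 25, "ASP", "protein", c(0, 2, 4)),
    atomspec("O", "OD2", 25, "ASP", "protein", c(1, 2, 4)))))
  ev <- suppressWarnings(
    detect_interactions(fr, 1, ligand_info = list(cations = 7)))
  expect_equal(sum(ev$kind == "pi_cation"), 1)
  expect_equal(ev$resno[ev$kind == "pi_cation"], 74)
  expect_true(any(ev$kind == "vdw" & ev$resno == 74))
  # ligand cation ~2.1 A from the aspartate carboxylate centroid
  expect_true(any(ev$kind == "salt_bridge" & ev$resno == 25))
})

test_that("interaction frequencies match a constructed schedule exactly", {
  frames <- lapply(1:10, function(f) {
    # h-bond present in frames 1-3 only (30%)
    d <- if (f <= 3) 2.8 else 6
    rbind(c(0, 0, 0), c(1.0, 0, 0), c(d, 0, 0))
  })
  top <- data.frame(element = c("O", "H", "O"), name = c("O1", "H1", "O"),
                    resno = c(900, 900, 41), resid = c("LIG", "LIG", "ARG"),
                    segment = c("ligand", "ligand", "protein"),
                    water_id = NA_integer_)
  tr <- trajectory(top, frames)
  fq <- interaction_frequencies(tr)
  hb <- fq[fq$kind == "hbond", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$frequency, 0.30)
  expect_true(all(fq$frequency >= 0 & fq$frequency <= 1))
})
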