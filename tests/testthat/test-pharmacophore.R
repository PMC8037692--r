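test_that("feature perception matches chemistry on anchor molecules", {
  benz <- embed_3d("c1ccccc1")
  f <- perceive_features(benz)
  expect_equal(sum(f$kind == "aromatic"), 1)
  expect_equal(sum(f$kind == "hbd"), 0)
  ctr <- colMeans(benz$xyz[benz$elements == "C", ])
  arow <- f[f$kind == "aromatic", ]
  expect_equal(unname(unlist(arow[, c("x", "y", "z")])), unname(ctr),
               tolerance = 1e-9)

  eth <- embed_3d("CCO")
  fe <- perceive_features(eth)
  expect_equal(sum(fe$kind == "hbd"), 1)
  expect_equal(sum(fe$kind == "hba"), 1)
  o_idx <- which(eth$elements == "O")
  expect_equal(unname(unlist(fe[fe$kind == "hbd", c("x", "y", "z")])),
               unname(eth$xyz[o_idx, ]), tolerance = 1e-9)
})

test_that("the THQ reference carries aromatic + two donors + one cation site", {
  f <- perceive_features(fix_ref_ligand())
  expect_equal(sum(f$kind == "aromatic"), 1)
  expect_equal(sum(f$kind == "hbd"), 2)
  expect_equal(sum(f$kind == "pos_ion"), 1)
  # positive centre sits on the ring nitrogen
  n_idx <- which(fix_ref_ligand()$elements == "N")
  expect_equal(unname(unlist(f[f$kind == "pos_ion", c("x", "y", "z")])),
               unname(fix_ref_ligand()$xyz[n_idx, ]), tolerance = 1e-9)
})

test_that("a single ligand yields its own features with support 1", {
  mdl <- build_ensemble_model(list(fix_ref_ligand()),
                              keep_kinds = c("aromatic", "hbd", "pos_ion"))
  expect_equal(nrow(mdl$features), 4)
  expect_true(all(mdl$features$support == 1))
})

test_that("the consensus model recovers planted feature centres", {
  ref <- fix_ref_ligand()
  truth <- perceive_features(ref)
  truth <- truth[truth$kind %in% c("aromatic", "hbd", "pos_ion"), ]
  ens <- gen_ligand_ensemble(ref, n = 21, sigma = 0.1, seed = 13)
  mdl <- build_ensemble_model(ens, keep_kinds = c("aromatic", "hbd", "pos_ion"))
  expect_equal(nrow(mdl$features), 4)
  expect_setequal(mdl$features$kind, c("aromatic", "hbd", "pos_ion"))
  expect_equal(sum(mdl$features$kind == "hbd"), 2)
  # each consensus centre within 0.15 A of its planted counterpart
  for (r in seq_len(nrow(mdl$features))) {
    cand <- truth[truth$kind == mdl$features$kind[r], ]
    d <- sqrt((cand$x - mdl$features$x[r])^2 +
                (cand$y - mdl$features$y[r])^2 +
                (cand$z - mdl$features$z[r])^2)
    expect_lt(min(d), 0.15)
  }
})

test_that("low-support features are excluded; huge noise breaks consensus", {
  ref <- fix_ref_ligand()
  ens <- gen_ligand_ensemble(ref, n = 21, sigma = 0.1, seed = 2)
  # add a 22nd ligand shifted far away: its features appear in 1/22 ligands
  stray <- ref
  stray$xyz <- stray$xyz + 30
  mdl <- build_ensemble_model(c(ens, list(stray)),
                              keep_kinds = c("aromatic", "hbd", "pos_ion"),
                              min_support = 0.5)
  expect_equal(nrow(mdl$features), 4)
  # sigma = 5 A: same-kind features no longer cluster at half support
  noisy <- gen_ligand_ensemble(ref, n = 21, sigma = 5, seed = 3)
  mdl2 <- build_ensemble_model(noisy, keep_kinds = c("aromatic", "hbd", "pos_ion"))
  expect_lt(nrow(mdl2$features), 4)
})

test_that("matching: identity is exact, translation misses, displacement is arithmetic", {
  ref <- fix_ref_ligand()
  mdl <- build_ensemble_model(list(ref),
                              keep_kinds = c("aromatic", "hbd", "pos_ion"))
  self <- match_conformer(ref, mdl)
  expect_true(self$matched)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)

  far <- ref; far$xyz <- far$xyz + c(5, 0, 0)
  expect_false(match_conformer(far, mdl)$matched)

  # displace the conformer's features by known vectors: rmsd is the
  # root-mean-square of those displacements; assignment checked brute force
  feats <- perceive_features(ref)
  feats <- feats[feats$kind %in% c("aromatic", "hbd", "pos_ion"), ]
  disp <- matrix(c(0.1, 0, 0, 0, 0.2, 0, 0, 0, 0.15, 0.05, 0.05, 0),
                 ncol = 3, byrow = TRUE)
  moved <- feats
  moved[, c("x", "y", "z")] <- as.matrix(feats[, c("x", "y", "z")]) + disp
  class(moved) <- c("pharm_features", "data.frame")
  m <- match_conformer(moved, mdl)
  expect_equal(m$rmsd, sqrt(mean(rowSums(disp^2))), tolerance = 1e-6)
})

test_that("a conformer lacking a required kind is unmatched with a reason", {
  ref <- fix_ref_ligand()
  mdl <- build_ensemble_model(list(ref),
                              keep_kinds = c("aromatic", "hbd", "pos_ion"))
  benz <- embed_3d("c1ccccc1")
  m <- match_conformer(benz, mdl)
  expect_false(m$matched)
  expect_match(m$reason, "lacks required kind")
})

test_that("screening finds exactly the planted matches and deduplicates compounds", {
  ref <- fix_ref_ligand()
  mdl <- build_ensemble_model(list(ref),
                              keep_kinds = c("aromatic", "hbd", "pos_ion"))
  near <- lapply(1:3, function(i) {
    m <- ref; m$xyz <- m$xyz + 0.02 * i; m
  })
  far <- lapply(1:4, function(i) {
    m <- ref; m$xyz <- m$xyz + 3 + i; m$name <- paste0("far", i); m
  })
  sets <- list(
    structure(list(compound = "hit", conformers = near, complete = TRUE,
                   n_requested = 3), class = "conformer_set"),
    structure(list(compound = "miss", conformers = far, complete = TRUE,
                   n_requested = 4), class = "conformer_set"))
  sr <- screen_library(sets, mdl, rmsd_threshold = 0.5)
  expect_equal(sr$n_conformer_hits, 3)
  expect_equal(sr$n_compound_hits, 1)
  expect_equal(sr$n_screened, 7)
  # monotonicity: tighter threshold cannot gain hits
  sr_tight <- screen_library(sets, mdl, rmsd_threshold = 0.1)
  expect_lte(sr_tight$n_conformer_hits, sr$n_conformer_hits)
  # raising min_support cannot add model features
  ens <- gen_ligand_ensemble(ref, n = 11, sigma = 0.1, seed = 4)
  m_lo <- build_ensemble_model(ens, keep_kinds = c("aromatic", "hbd", "pos_ion"),
                               min_support = 0.3)
  m_hi <- build_ensemble_model(ens, keep_kinds = c("aromatic", "hbd", "pos_ion"),
                               min_support = 0.9)
  expect_lte(nrow(m_hi$features), nrow(m_lo$features))
})

test_that("a library with no cationic site never matches a cation-bearing model", {
  ref <- fix_ref_ligand()
  mdl <- build_ensemble_model(list(ref),
                              keep_kinds = c("aromatic", "hbd", "pos_ion"))
  benz <- embed_3d("c1ccccc1"); benz$name <- "benzene"
  phen <- embed_3d("Oc1ccccc1"); phen$name <- "phenol"
  sr <- screen_library(list(list(benz), list(phen)), mdl)
  expect_equal(sr$n_conformer_hits, 0)
})

test_that("model JSON persistence round-trips", {
  ref <- fix_ref_ligand()
  mdl <- build_ensemble_model(gen_ligand_ensemble(ref, 5, 0.05, seed = 6),
                              keep_kinds = c("aromatic", "hbd", "pos_ion"))
  path <- tempfile(fileext = ".json")
  write_pharmacophore(mdl, path)
  back <- read_pharmacophore(path)
  expect_equal(back$features$kind, mdl$features$kind)
  expect_equal(back$features$x, mdl$features$x, tolerance = 1e-12)
  expect_equal(back$min_support, mdl$min_support)
  m <- match_conformer(ref, back)
  expect_true(m$matched)
})
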