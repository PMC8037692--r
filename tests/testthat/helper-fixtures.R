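# Shared fixtures. Expensive objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

fix_ref_ligand <- function() cached("ref_ligand", reference_thq_ligand())

fix_small_blocks <- function() {
  cached("small_blocks", {
    load_building_blocks(gen_building_blocks(n_thq = 3, n_ald = 2, n_iso = 4))
  })
}

fix_small_library <- function() {
  cached("small_library", enumerate_library(fix_small_blocks(), "ugi_3cr"))
}

fix_conformers_can125 <- function() {
  cached("conf_can125", {
    generate_conformers("OCC(N1CCc2c(C)cccc2C1)C(=O)NCc1cccc(O)c1",
                        n = 10, seed = 42)
  })
}

# Independent brute-force substructure matcher: recursive backtracking over
# adjacency-preserving injective maps (no igraph), used as the oracle for
# substructure RMSD minimization.
oracle_substructure_maps <- function(pat_el, pat_bonds, mol_el, mol_bonds) {
  np <- length(pat_el)
  adj_p <- matrix(0L, np, np)
  for (r in seq_len(nrow(pat_bonds))) {
    adj_p[pat_bonds$a1[r], pat_bonds$a2[r]] <- pat_bonds$order[r]
    adj_p[pat_bonds$a2[r], pat_bonds$a1[r]] <- pat_bonds$order[r]
  }
  nm <- length(mol_el)
  adj_m <- matrix(0L, nm, nm)
  for (r in seq_len(nrow(mol_bonds))) {
    adj_m[mol_bonds$a1[r], mol_bonds$a2[r]] <- mol_bonds$order[r]
    adj_m[mol_bonds$a2[r], mol_bonds$a1[r]] <- mol_bonds$order[r]
  }
  maps <- list()
  assign_next <- function(map) {
    k <- length(map) + 1L
    if (k > np) {
      maps[[length(maps) + 1L]] <<- map
      return(invisible())
    }
    for (cand in seq_len(nm)) {
      if (cand %in% map) next
      if (mol_el[cand] != pat_el[k]) next
      ok <- TRUE
      for (prev in seq_len(k - 1L)) {
        if (adj_p[k, prev] > 0 && adj_m[cand, map[prev]] == 0) { ok <- FALSE; break }
        if (adj_p[k, prev] == 0 && adj_m[cand, map[prev]] > 0) { ok <- FALSE; break }
      }
      if (ok) assign_next(c(map, cand))
    }
  }
  assign_next(integer(0))
  maps
}

# Oracle in-place minimum RMSD over all pattern embeddings in both
# structures (heavy atoms only).
oracle_min_rmsd <- function(pose, reference, pattern_mol) {
  hp <- which(pose$elements != "H"); hr <- which(reference$elements != "H")
  sub_bonds <- function(mol, keep) {
    idx <- match(seq_along(mol$elements), keep)
    b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, ]
    data.frame(a1 = idx[b$a1], a2 = idx[b$a2], order = b$order)
  }
  pe <- pattern_mol$elements; pb <- pattern_mol$bonds
  mp <- oracle_substructure_maps(pe, pb, pose$elements[hp], sub_bonds(pose, hp))
  mr <- oracle_substructure_maps(pe, pb, reference$elements[hr],
                                 sub_bonds(reference, hr))
  best <- Inf
  for (m1 in mr) {
    rx <- reference$xyz[hr[m1], , drop = FALSE]
    for (m2 in mp) {
      px <- pose$xyz[hp[m2], , drop = FALSE]
      best <- min(best, sqrt(mean(rowSums((px - rx)^2))))
    }
  }
  best
}

# Horn quaternion absolute-orientation solver: independent closed-form
# oracle for the Kabsch superposition RMSD.
oracle_superpose_rmsd <- function(mobile, ref) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  M <- crossprod(A, B)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE)$values)
  ss <- sum(A^2) + sum(B^2) - 2 * lam
  sqrt(max(0, ss) / nrow(mobile))
}

# A mol3d from explicit pieces, quickly.
quick_mol <- function(elements, xyz, bonds = NULL) {
  if (is.null(bonds)) bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                                          order = integer(0))
  mol3d(elements, xyz, bonds)
}
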