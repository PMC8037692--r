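# Conformer expansion: deterministic 3D embedding (OpenBabel OBBuilder,
# `--gen3d fast`), seeded torsion sampling, MMFF94 relaxation and energy
# ranking. "Energetically favorable" here means the lowest-energy n distinct
# conformers under MMFF94 after relaxation.

#' Generate a ranked conformer set
#'
#' Embeds the molecule in 3D, perturbs all rotatable-bond torsions over a
#' seeded candidate pool, relaxes every candidate with MMFF94 and keeps the
#' `n` lowest-energy conformers that are mutually distinct (heavy-atom RMSD
#' after optimal superposition above `dedup_rmsd`). When distinctness is
#' unreachable (rigid molecules) the set is flagged incomplete.
#'
#' @param smiles A single SMILES string.
#' @param n Target number of conformers (default 20, the screening
#'   expansion depth).
#' @param seed Integer seed; the whole pipeline is deterministic given it.
#' @param n_candidates Torsion-sampled candidates to relax.
#' @param dedup_rmsd Distinctness threshold in Angstrom.
#' @param minimize_steps MMFF94 steepest-descent steps per candidate.
#' @return A `conformer_set`: list with `compound` (SMILES), `conformers`
#'   (list of [mol3d()], energies relative to the best, sorted
#'   non-decreasing), `complete` flag and `n_requested`.
#' @export
generate_conformers <- function(smiles, n = 20, seed = 1,
                                n_candidates = max(3L * n, 30L),
                                dedup_rmsd = 0.1, minimize_steps = 200) {
  stopifnot(length(smiles) == 1, n >= 1)
  base <- embed_3d(smiles)
  if (is.null(base)) {
    stop("3D embedding failed for ", smiles, call. = FALSE)
  }
  rot <- rotatable_bonds(base)
  cands <- list(base)
  if (nrow(rot) > 0 && n_candidates > 1) {
    angles <- c(-150, -90, -30, 30, 90, 150) * pi / 180
    draws <- with_seed(seed, matrix(sample.int(length(angles),
                                               (n_candidates - 1L) * nrow(rot),
                                               replace = TRUE),
                                    nrow = n_candidates - 1L))
    for (k in seq_len(n_candidates - 1L)) {
      m <- base
      for (b in seq_len(nrow(rot))) {
        m <- twist_bond(m, rot$a1[b], rot$a2[b], rot$side[[b]],
                        angles[draws[k, b]])
      }
      cands[[k + 1L]] <- m
    }
  }
  relaxed <- mmff_relax(cands, steps = minimize_steps)
  ord <- order(vapply(relaxed, function(m) m$energy, numeric(1)))
  relaxed <- relaxed[ord]
  heavy <- heavy_atoms(base)
  kept <- list()
  for (m in relaxed) {
    distinct <- all(vapply(kept, function(k2) {
      rmsd_coords(m$xyz[heavy, , drop = FALSE],
                  k2$xyz[heavy, , drop = FALSE], superpose = TRUE) > dedup_rmsd
    }, logical(1)))
    if (distinct) kept[[length(kept) + 1L]] <- m
    if (length(kept) == n) break
  }
  e0 <- kept[[1]]$energy
  kept <- lapply(seq_along(kept), function(i) {
    m <- kept[[i]]
    m$energy <- m$energy - e0
    m$name <- paste0(m$name, "_conf", i)
    m
  })
  structure(list(compound = smiles, conformers = kept,
                 complete = length(kept) == n, n_requested = n),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat("conformer_set:", length(x$conformers), "of", x$n_requested,
      "conformers", if (!x$complete) "(incomplete)", "for", x$compound, "\n")
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic 3D embedding with explicit hydrogens: the deterministic 2D
# layout engine supplies the topology-faithful starting geometry, a fixed
# sinusoidal out-of-plane perturbation breaks planarity (an exactly planar
# start is a saddle point of the force field), and MMFF94 steepest descent
# relaxes the result. Stochastic 3D builders are avoided on purpose: the
# conformer contract requires bit-reproducible sets under a fixed seed.
embed_3d <- function(smiles, pucker = 0.4, steps = 1500) {
  tmp_in <- tempfile(fileext = ".smi"); tmp_out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(paste(smiles, "mol"), tmp_in)
  system2(ob_binary(), c(tmp_in, "-O", tmp_out, "--gen2d", "-h"),
          stdout = FALSE, stderr = FALSE)
  mols <- tryCatch(read_sdf_mols(tmp_out), error = function(e) list())
  if (length(mols) == 0) return(NULL)
  m <- mols[[1]]
  m$xyz[, 3] <- pucker * sin(seq_along(m$elements))
  relaxed <- tryCatch(mmff_relax(list(m), steps = steps),
                      error = function(e) NULL)
  if (is.null(relaxed)) return(NULL)
  relaxed[[1]]
}

# Rotatable bonds: acyclic single bonds between non-terminal heavy atoms,
# excluding amide C-N. Returns a data frame with the atom pair and the list
# of atoms on the a2 side (the set rotated by twist_bond).
rotatable_bonds <- function(mol) {
  g <- mol3d_graph(mol)
  bridges <- igraph::bridges(g)
  el <- mol$elements
  hdeg <- vapply(seq_along(el), function(v) {
    sum(el[as.integer(igraph::neighbors(g, v))] != "H")
  }, integer(1))
  out <- data.frame(a1 = integer(0), a2 = integer(0))
  sides <- list()
  for (eid in as.integer(bridges)) {
    ends <- as.integer(igraph::ends(g, eid, names = FALSE))
    a1 <- ends[1]; a2 <- ends[2]
    if (igraph::E(g)$order[eid] != 1) next
    if (el[a1] == "H" || el[a2] == "H") next
    if (hdeg[a1] < 2 || hdeg[a2] < 2) next
    if (is_amide_bond(g, el, a1, a2)) next
    g2 <- igraph::delete_edges(g, eid)
    comp <- igraph::components(g2)$membership
    side <- which(comp == comp[a2])
    # rotate the smaller side for numerical tidiness
    if (length(side) > length(el) / 2) side <- which(comp == comp[a1])
    out <- rbind(out, data.frame(a1 = a1, a2 = a2))
    sides[[length(sides) + 1L]] <- setdiff(side, c(a1, a2))
  }
  out$side <- sides
  out
}

is_amide_bond <- function(g, el, a1, a2) {
  pair <- list(c(a1, a2), c(a2, a1))
  for (p in pair) {
    if (el[p[1]] == "C" && el[p[2]] == "N") {
      for (nb in as.integer(igraph::neighbors(g, p[1]))) {
        eid <- igraph::get_edge_ids(g, c(p[1], nb))
        if (el[nb] == "O" && igraph::E(g)$order[eid] == 2) return(TRUE)
      }
    }
  }
  FALSE
}

# Rotate `side` atoms about the a1->a2 axis by `angle`.
twist_bond <- function(mol, a1, a2, side, angle) {
  if (length(side) == 0) return(mol)
  mol$xyz[side, ] <- rotate_about_axis(mol$xyz[side, , drop = FALSE],
                                       mol$xyz[a1, ], mol$xyz[a2, ], angle)
  mol
}

# Batch MMFF94 relaxation + energy evaluation through the OpenBabel CLI.
mmff_relax <- function(mols, steps = 200) {
  tmp_in <- tempfile(fileext = ".sdf"); tmp_out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  write_sdf_mols(mols, tmp_in)
  system2(ob_binary(), c(tmp_in, "-O", tmp_out, "--minimize", "--ff", "MMFF94",
                         "--steps", steps, "--sd"),
          stdout = FALSE, stderr = FALSE)
  relaxed <- read_sdf_mols(tmp_out)
  if (length(relaxed) != length(mols)) {
    stop("MMFF94 relaxation dropped candidates", call. = FALSE)
  }
  en <- system2(ob_binary("obenergy"), c("-ff", "MMFF94", tmp_out),
                stdout = TRUE, stderr = FALSE)
  en <- en[grepl("TOTAL ENERGY", en, fixed = TRUE)]
  vals <- as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1", en))
  if (length(vals) != length(relaxed)) {
    stop("energy evaluation failed", call. = FALSE)
  }
  Map(function(m, e) { m$energy <- e; m }, relaxed, vals)
}

#' Total conformer count over libraries
#'
#' The count identity used for the screening expansion: with no embedding
#' failures, total conformers = n_per_compound x total compounds.
#'
#' @param library_sizes Integer vector of unique-compound counts per library.
#' @param n_per_compound Conformers generated per compound.
#' @return Total conformer count.
#' @export
conformer_expansion_count <- function(library_sizes, n_per_compound = 20) {
  stopifnot(all(library_sizes >= 0), n_per_compound >= 1)
  sum(as.numeric(library_sizes)) * n_per_compound
}
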