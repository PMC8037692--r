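# Physicochemical and shape descriptors.
#
# A fixed roster of 30 descriptors: 21 two-dimensional (composition, rings,
# flexibility, topology, and the five drug-likeness quantities MW, LogP,
# TPSA, HBD, HBA) and 9 three-dimensional shape quantities computed on the
# minimum-energy conformer (principal moments of inertia and derived ratios).
# LogP, TPSA and molar refractivity come from OpenBabel's additive models;
# HBD/HBA use the classic Lipinski definitions (N/O bearing hydrogen; N + O
# count).

DESCRIPTOR_2D <- c("MW", "LogP", "TPSA", "HBD", "HBA", "MR",
                   "heavy_atoms", "n_C", "n_N", "n_O", "n_halogen",
                   "n_hetero", "n_rings", "n_aromatic_atoms", "n_ring_atoms",
                   "n_rotatable", "frac_csp3", "n_amide", "n_bonds",
                   "graph_diameter", "wiener_index")
DESCRIPTOR_3D <- c("PMI1", "PMI2", "PMI3", "NPR1", "NPR2",
                   "radius_of_gyration", "asphericity", "eccentricity", "span")
DESCRIPTOR_ROSTER <- c(DESCRIPTOR_2D, DESCRIPTOR_3D)

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                 P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
                 B = 10.81, Si = 28.085)

#' Compute the 30-descriptor table for a set of compounds
#'
#' @param smiles Character vector of SMILES (e.g. `canonical_key` of a
#'   [enumerate_library()] result).
#' @param conformers Optional list of `conformer_set` objects (same order);
#'   3D descriptors use each set's minimum-energy conformer and are `NA`
#'   when absent.
#' @param ids Row identifiers (defaults to names or index).
#' @return A `descriptor_table` data frame: one row per compound, 30
#'   descriptor columns plus `id` and a logical `flag` column marking rows
#'   where any descriptor failed (rows are flagged, never dropped).
#' @export
compute_descriptors <- function(smiles, conformers = NULL, ids = NULL) {
  stopifnot(is.character(smiles))
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    paste0("cpd", seq_along(smiles))
  rows <- lapply(seq_along(smiles), function(i) {
    d2 <- tryCatch(descriptors_2d(smiles[i]), error = function(e) NULL)
    mol <- if (!is.null(conformers)) min_energy_conformer(conformers[[i]]) else NULL
    d3 <- if (!is.null(mol)) {
      tryCatch(shape_descriptors(mol), error = function(e) NULL)
    } else NULL
    vals <- setNames(rep(NA_real_, length(DESCRIPTOR_ROSTER)), DESCRIPTOR_ROSTER)
    if (!is.null(d2)) vals[names(d2)] <- d2
    if (!is.null(d3)) vals[names(d3)] <- d3
    failed <- is.null(d2) || (!is.null(conformers) && is.null(d3))
    c(list(id = ids[i], flag = failed), as.list(vals))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  class(out) <- c("descriptor_table", "data.frame")
  out
}

min_energy_conformer <- function(cs) {
  if (is.null(cs)) return(NULL)
  if (inherits(cs, "mol3d")) return(cs)
  if (inherits(cs, "conformer_set") && length(cs$conformers)) {
    return(cs$conformers[[1]])   # sets are sorted by energy
  }
  NULL
}

# 2D roster from the molecular graph + OpenBabel additive models.
descriptors_2d <- function(smi) {
  can <- canonical_smiles(smi)
  if (is.na(can)) stop("unparsable SMILES")
  props <- ChemmineOB::forEachMol("SMI", can, function(m) {
    ChemmineOB::prop_OB(list(m))
  })[[1]]
  g <- mol_graph(can)
  el <- igraph::V(g)$element
  orders <- igraph::E(g)$order
  hcount <- implicit_hydrogens(g)
  heavy <- el != "H"
  aromatic <- aromatic_atoms(g)
  in_ring <- ring_atoms(g)
  n_comp <- igraph::components(g)$no
  n_rings <- igraph::ecount(g) - igraph::vcount(g) + n_comp
  rot <- rotatable_bond_count(g, hcount)
  csp3 <- sum(el == "C" & vapply(seq_along(el), function(v) {
    eids <- igraph::incident(g, v)
    all(igraph::E(g)$order[as.integer(eids)] == 1)
  }, logical(1)))
  dmat <- igraph::distances(g)
  c(MW = as.numeric(props[["MW"]]),
    LogP = as.numeric(props[["logP"]]),
    TPSA = as.numeric(props[["TPSA"]]),
    HBD = sum(el %in% c("N", "O") & hcount > 0),
    HBA = sum(el %in% c("N", "O")),
    MR = as.numeric(props[["MR"]]),
    heavy_atoms = sum(heavy),
    n_C = sum(el == "C"), n_N = sum(el == "N"), n_O = sum(el == "O"),
    n_halogen = sum(el %in% c("F", "Cl", "Br", "I")),
    n_hetero = sum(heavy & !el %in% "C"),
    n_rings = n_rings,
    n_aromatic_atoms = sum(aromatic),
    n_ring_atoms = sum(in_ring),
    n_rotatable = rot,
    frac_csp3 = if (sum(el == "C") > 0) csp3 / sum(el == "C") else 0,
    n_amide = smarts_count(can, "[CX3](=[OX1])[NX3]"),
    n_bonds = igraph::ecount(g),
    graph_diameter = max(dmat[is.finite(dmat)]),
    wiener_index = sum(dmat[upper.tri(dmat)][is.finite(dmat[upper.tri(dmat)])]))
}

# Implicit hydrogen counts from standard valences (connection tables from
# SMILES carry no explicit hydrogens).
implicit_hydrogens <- function(g) {
  valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L, Cl = 1L,
               Br = 1L, I = 1L, B = 3L)
  el <- igraph::V(g)$element
  vapply(seq_along(el), function(v) {
    vt <- valence[el[v]]
    if (is.na(vt)) return(0L)
    bsum <- sum(igraph::E(g)$order[as.integer(igraph::incident(g, v))])
    max(0L, as.integer(vt) - as.integer(bsum))
  }, integer(1))
}

# Ring membership: vertices on edges that are not bridges.
ring_atoms <- function(g) {
  ring_edges <- setdiff(seq_len(igraph::ecount(g)),
                        as.integer(igraph::bridges(g)))
  v <- rep(FALSE, igraph::vcount(g))
  if (length(ring_edges)) {
    ends <- igraph::ends(g, ring_edges, names = FALSE)
    v[unique(as.integer(ends))] <- TRUE
  }
  v
}

# Aromatic atoms, approximated from the Kekule table: ring atoms carrying a
# double bond to another ring atom within a ring system of sp2 centres.
aromatic_atoms <- function(g) {
  in_ring <- ring_atoms(g)
  el <- igraph::V(g)$element
  out <- rep(FALSE, length(el))
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  dbl <- igraph::E(g)$order == 2
  for (k in which(dbl)) {
    a <- ends[k, 1]; b <- ends[k, 2]
    if (in_ring[a] && in_ring[b]) { out[a] <- TRUE; out[b] <- TRUE }
  }
  # ring heteroatoms flanked by two flagged atoms (pyrrole-type N, furan O)
  repeat {
    added <- FALSE
    for (v in which(in_ring & !out & el %in% c("N", "O", "S"))) {
      nb <- as.integer(igraph::neighbors(g, v))
      if (sum(out[nb]) >= 2) { out[v] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }
  out
}

rotatable_bond_count <- function(g, hcount) {
  el <- igraph::V(g)$element
  bridges <- as.integer(igraph::bridges(g))
  deg <- igraph::degree(g)
  n <- 0L
  for (eid in bridges) {
    if (igraph::E(g)$order[eid] != 1) next
    ends <- as.integer(igraph::ends(g, eid, names = FALSE))
    if (any(el[ends] == "H")) next
    if (any(deg[ends] < 2)) next
    if (is_amide_bond(g, el, ends[1], ends[2])) next
    n <- n + 1L
  }
  n
}

#' Principal-moment shape descriptors of a conformer
#'
#' Moments of inertia use atomic masses; `NPR1 = I1/I3`, `NPR2 = I2/I3`
#' with `I1 <= I2 <= I3`, placing every conformer inside the rod-disc-sphere
#' triangle (`NPR1 <= NPR2 <= 1`, `NPR1 + NPR2 >= 1`).
#'
#' @param mol A [mol3d()].
#' @return Named numeric vector of the 9 shape descriptors.
#' @export
shape_descriptors <- function(mol) {
  mass <- ATOMIC_MASS[mol$elements]
  mass[is.na(mass)] <- 12
  xyz <- mol$xyz
  com <- colSums(xyz * mass) / sum(mass)
  X <- sweep(xyz, 2, com)
  Ixx <- sum(mass * (X[, 2]^2 + X[, 3]^2))
  Iyy <- sum(mass * (X[, 1]^2 + X[, 3]^2))
  Izz <- sum(mass * (X[, 1]^2 + X[, 2]^2))
  Ixy <- -sum(mass * X[, 1] * X[, 2])
  Ixz <- -sum(mass * X[, 1] * X[, 3])
  Iyz <- -sum(mass * X[, 2] * X[, 3])
  I <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
  pmi <- sort(abs(eigen(I, symmetric = TRUE)$values))
  npr1 <- if (pmi[3] > 0) pmi[1] / pmi[3] else 0
  npr2 <- if (pmi[3] > 0) pmi[2] / pmi[3] else 1
  # gyration tensor (unit mass) quantities
  Xc <- sweep(xyz, 2, colMeans(xyz))
  S <- crossprod(Xc) / nrow(Xc)
  lam <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
  rg <- sqrt(sum(lam))
  asph <- lam[1] - 0.5 * (lam[2] + lam[3])
  ecc <- if (pmi[3] > 0) sqrt(max(0, pmi[3]^2 - pmi[1]^2)) / pmi[3] else 0
  c(PMI1 = pmi[1], PMI2 = pmi[2], PMI3 = pmi[3],
    NPR1 = npr1, NPR2 = npr2,
    radius_of_gyration = rg, asphericity = asph, eccentricity = ecc,
    span = max(sqrt(rowSums(Xc^2))))
}

#' Classify a conformer in the rod-disc-sphere triangle
#'
#' Nearest vertex among rod (0, 1), disc (0.5, 0.5) and sphere (1, 1) by
#' Euclidean distance in the (NPR1, NPR2) plane.
#'
#' @param npr1,npr2 Normalized principal-moment ratios.
#' @param tol Tolerance for the triangle-membership check.
#' @return `"rod"`, `"disc"` or `"sphere"` (vectorized).
#' @export
classify_shape <- function(npr1, npr2, tol = 1e-6) {
  stopifnot(length(npr1) == length(npr2))
  bad <- npr1 + npr2 < 1 - tol | npr1 > npr2 + tol | npr2 > 1 + tol
  if (any(bad, na.rm = TRUE)) {
    stop("point(s) outside the NPR triangle (NPR1 <= NPR2 <= 1, NPR1 + NPR2 >= 1)",
         call. = FALSE)
  }
  verts <- rbind(rod = c(0, 1), disc = c(0.5, 0.5), sphere = c(1, 1))
  vapply(seq_along(npr1), function(i) {
    d2 <- (verts[, 1] - npr1[i])^2 + (verts[, 2] - npr2[i])^2
    rownames(verts)[which.min(d2)]
  }, character(1))
}

#' Extended rule-of-five evaluation
#'
#' Classic limits (MW <= 500 Da, LogP <= 5, HBD <= 5, HBA <= 10) extended
#' with a polar-surface-area limit (TPSA <= 140 A^2). A compound passes when
#' every rule holds; compounds with missing descriptors get `NA` flags and
#' are excluded from the pass rate.
#'
#' @param table A `descriptor_table` (or data frame with the five columns).
#' @param limits Named numeric vector of upper limits, configurable.
#' @return List with `flags` (per-compound logical data frame), `pass`
#'   (logical vector) and `pass_rate` (fraction of evaluable compounds).
#' @export
ro5_extended <- function(table,
                         limits = c(MW = 500, LogP = 5, HBD = 5, HBA = 10,
                                    TPSA = 140)) {
  stopifnot(all(names(limits) %in% names(table)))
  flags <- as.data.frame(lapply(names(limits), function(d) {
    table[[d]] <= limits[[d]]
  }))
  names(flags) <- paste0(names(limits), "_ok")
  pass <- Reduce(`&`, flags)
  list(flags = cbind(id = table$id, flags), pass = pass,
       pass_rate = mean(pass, na.rm = TRUE))
}
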