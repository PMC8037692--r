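# Ligand-target interaction detection with standard geometric cutoffs
# (hydrogen bond, water bridge, pi-cation, hydrophobic/van der Waals
# contact, salt bridge), and per-residue frequency aggregation over a
# trajectory.

#' Default interaction cutoffs
#'
#' Hydrogen bond: donor-acceptor heavy-atom distance <= 3.5 A, with a
#' donor-H-acceptor angle >= 130 degrees when hydrogens are present; water
#' bridge: one water hydrogen-bonded to ligand and residue simultaneously;
#' pi-cation: cation to aromatic-ring centroid <= 6.0 A; van der Waals
#' (hydrophobic) contact: ligand-residue carbon pair <= 4.0 A; salt bridge:
#' opposite formal-charge centroids <= 5.5 A.
#'
#' @return Named list of cutoffs (distances in Angstrom, angle in degrees).
#' @export
interaction_cutoffs <- function() {
  list(hbond_dist = 3.5, hbond_angle = 130,
       pi_cation = 6.0, vdw = 4.0, salt_bridge = 5.5)
}

# Protein side-chain feature atoms by residue type.
PROT_CATION_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                          HIS = c("ND1", "NE2"))
PROT_ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
PROT_AROMATIC_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

#' Detect ligand-protein interactions in one frame
#'
#' @param traj A [trajectory()].
#' @param frame Frame index.
#' @param ligand_info Optional list describing the ligand's typed atoms
#'   (indices into the trajectory's atom table): `cations`, `anions`,
#'   `rings` (list of index vectors). Polar ligand atoms (N/O) are found
#'   from the topology automatically.
#' @param cutoffs Cutoff list, see [interaction_cutoffs()].
#' @return An `interaction_events` data frame: `frame`, `resno`, `resid`,
#'   `kind`, `distance`, `angle` (`NA` where not applicable).
#' @export
detect_interactions <- function(traj, frame = 1, ligand_info = NULL,
                                cutoffs = interaction_cutoffs()) {
  top <- traj$topology
  xyz <- traj$frames[[frame]]
  lig <- which(top$segment == "ligand")
  prot <- which(top$segment == "protein")
  if (length(lig) == 0 || length(prot) == 0) {
    stop("frame needs both ligand and protein atoms", call. = FALSE)
  }
  ev <- list()
  add <- function(resno, kind, distance, angle = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      frame = frame, resno = resno,
      resid = top$resid[match(resno, top$resno)], kind = kind,
      distance = distance, angle = angle)
  }
  has_h <- any(top$element == "H")
  if (!has_h) {
    warning("no hydrogens in topology; hydrogen bonds use the heavy-atom ",
            "distance criterion only", call. = FALSE)
  }
  lig_polar <- lig[top$element[lig] %in% c("N", "O")]
  prot_polar <- prot[top$element[prot] %in% c("N", "O")]

  # hydrogen bonds (ligand polar atom vs protein polar atom)
  for (a in lig_polar) {
    for (b in prot_polar) {
      d <- dist3(xyz[a, ], xyz[b, ])
      if (d > cutoffs$hbond_dist) next
      ang <- NA_real_
      if (has_h) {
        ang <- best_dha_angle(xyz, top, a, b)
        if (!is.na(ang) && ang < cutoffs$hbond_angle) next
      }
      add(top$resno[b], "hbond", d, ang)
    }
  }

  # water bridges: a water oxygen h-bonded to both sides
  wo <- sel_water_o(top)
  for (w in wo) {
    dl <- if (length(lig_polar)) {
      min(vapply(lig_polar, function(a) dist3(xyz[w, ], xyz[a, ]), numeric(1)))
    } else Inf
    if (dl > cutoffs$hbond_dist) next
    for (b in prot_polar) {
      d <- dist3(xyz[w, ], xyz[b, ])
      if (d <= cutoffs$hbond_dist) add(top$resno[b], "water_bridge", max(d, dl))
    }
  }

  # pi-cation: ligand cation vs protein aromatic ring, and protein cation vs
  # ligand ring
  prot_res <- unique(top$resno[prot])
  for (r in prot_res) {
    resid <- top$resid[match(r, top$resno)]
    arom <- PROT_AROMATIC_ATOMS[[resid]]
    if (!is.null(arom) && !is.null(ligand_info$cations)) {
      ring_idx <- prot[top$resno[prot] == r & top$name[prot] %in% arom]
      if (length(ring_idx) >= 3) {
        ctr <- colMeans(xyz[ring_idx, , drop = FALSE])
        for (c_at in ligand_info$cations) {
          d <- dist3(xyz[c_at, ], ctr)
          if (d <= cutoffs$pi_cation) add(r, "pi_cation", d)
        }
      }
    }
    cat_atoms <- PROT_CATION_ATOMS[[resid]]
    if (!is.null(cat_atoms) && length(ligand_info$rings)) {
      ci <- prot[top$resno[prot] == r & top$name[prot] %in% cat_atoms]
      for (ring in ligand_info$rings) {
        ctr <- colMeans(xyz[ring, , drop = FALSE])
        for (c_at in ci) {
          d <- dist3(xyz[c_at, ], ctr)
          if (d <= cutoffs$pi_cation) add(r, "pi_cation", d)
        }
      }
    }
  }

  # van der Waals / hydrophobic carbon contacts (one event per residue-frame)
  lig_c <- lig[top$element[lig] == "C"]
  prot_c <- prot[top$element[prot] == "C"]
  if (length(lig_c) && length(prot_c)) {
    for (r in prot_res) {
      ci <- prot_c[top$resno[prot_c] == r]
      if (!length(ci)) next
      dmin <- min(apply(xyz[ci, , drop = FALSE], 1, function(p) {
        min(vapply(lig_c, function(a) dist3(xyz[a, ], p), numeric(1)))
      }))
      if (dmin <= cutoffs$vdw) add(r, "vdw", dmin)
    }
  }

  # salt bridges
  salt <- function(lig_atoms, prot_map) {
    for (r in prot_res) {
      resid <- top$resid[match(r, top$resno)]
      atoms <- prot_map[[resid]]
      if (is.null(atoms) || is.null(lig_atoms) || !length(lig_atoms)) next
      pi <- prot[top$resno[prot] == r & top$name[prot] %in% atoms]
      if (!length(pi)) next
      ctr_p <- colMeans(xyz[pi, , drop = FALSE])
      ctr_l <- colMeans(xyz[lig_atoms, , drop = FALSE])
      d <- dist3(ctr_p, ctr_l)
      if (d <= cutoffs$salt_bridge) add(r, "salt_bridge", d)
    }
  }
  salt(ligand_info$cations, PROT_ANION_ATOMS)
  salt(ligand_info$anions, PROT_CATION_ATOMS)

  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(frame = integer(0), resno = integer(0), resid = character(0),
               kind = character(0), distance = numeric(0), angle = numeric(0))
  class(out) <- c("interaction_events", "data.frame")
  out
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Best donor-H-acceptor angle over hydrogens covalently attached (< 1.25 A)
# to either polar end; NA when neither end carries a hydrogen.
best_dha_angle <- function(xyz, top, a, b) {
  hs <- which(top$element == "H")
  best <- NA_real_
  for (don in c(a, b)) {
    acc <- if (don == a) b else a
    dh <- hs[vapply(hs, function(h) dist3(xyz[h, ], xyz[don, ]) < 1.25,
                    logical(1))]
    for (h in dh) {
      v1 <- xyz[don, ] - xyz[h, ]
      v2 <- xyz[acc, ] - xyz[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (is.na(best) || ang > best) best <- ang
    }
  }
  best
}

#' Interaction frequencies over a trajectory
#'
#' Fraction of frames in which each (residue, kind) pair shows at least one
#' event. Kinds are not exclusive; rows do not sum to one.
#'
#' @param traj A [trajectory()].
#' @param ligand_info,cutoffs Passed to [detect_interactions()].
#' @param frames Frame indices to analyse (default all).
#' @return Data frame: `resno`, `resid`, `kind`, `frequency` in `[0, 1]`.
#' @export
interaction_frequencies <- function(traj, ligand_info = NULL,
                                    cutoffs = interaction_cutoffs(),
                                    frames = seq_along(traj$frames)) {
  stopifnot(length(frames) >= 1)
  tabs <- lapply(frames, function(f) {
    ev <- suppressWarnings(
      detect_interactions(traj, f, ligand_info, cutoffs))
    unique(ev[, c("resno", "resid", "kind")])
  })
  all_ev <- do.call(rbind, tabs)
  if (nrow(all_ev) == 0) {
    return(data.frame(resno = integer(0), resid = character(0),
                      kind = character(0), frequency = numeric(0)))
  }
  agg <- aggregate(list(count = rep(1L, nrow(all_ev))),
                   by = all_ev[, c("resno", "resid", "kind")], FUN = sum)
  agg$frequency <- agg$count / length(frames)
  agg$count <- NULL
  agg[order(agg$resno, agg$kind), ]
}
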