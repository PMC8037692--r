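# Seeded synthetic-data generators for the remaining pipeline stages:
# aligned ligand ensembles, docking pose sets with a planted match count,
# toy MD trajectories (rigid helix + ligand + random-walking waters) and
# per-frame energy tables with an exact per-residue partition. These are
# contract fixtures: statistically controlled, bit-reproducible under a
# fixed seed, with ground truth carried alongside; physical realism of
# dynamics and energetics is out of scope.

#' Reference tetrahydroisoquinoline ligand
#'
#' A deterministic 3D conformer of 6-hydroxy-THQ: one aromatic ring, two
#' hydrogen-bond donors (phenol OH, ring NH) and one protonatable ring
#' nitrogen -- the four-feature reference used by the ensemble-model
#' recovery fixtures.
#'
#' @return A [mol3d()].
#' @export
reference_thq_ligand <- function() {
  mol <- embed_3d("Oc1ccc2c(c1)CCNC2")
  if (is.null(mol)) stop("embedding of the reference ligand failed",
                         call. = FALSE)
  mol$name <- "thq_ref"
  mol
}

#' Generate an aligned noisy ligand ensemble
#'
#' `n` copies of the reference with i.i.d. Gaussian per-coordinate
#' displacement of standard deviation `sigma`, emulating an aligned
#' crystallographic ligand series sharing a binding mode.
#'
#' @param reference A [mol3d()] (default [reference_thq_ligand()]).
#' @param n Ensemble size (default 21, the co-crystal series size).
#' @param sigma Per-coordinate noise SD in Angstrom (default 0.1, sub-Angstrom
#'   spread).
#' @param seed Integer seed.
#' @return List of `n` [mol3d()] objects.
#' @export
gen_ligand_ensemble <- function(reference = reference_thq_ligand(), n = 21,
                                sigma = 0.1, seed = 1) {
  stopifnot(n >= 1, sigma >= 0)
  with_seed(seed, lapply(seq_len(n), function(i) {
    m <- reference
    m$xyz <- m$xyz + matrix(rnorm(length(m$xyz), sd = sigma),
                            nrow(m$xyz), 3)
    m$name <- paste0(reference$name, "_copy", i)
    m
  }))
}

#' Generate a docking pose set with a planted match count
#'
#' Builds `N` rigid translations of the reference: `k` by a displacement
#' drawn below the RMSD threshold, `N - k` by a displacement of at least
#' `threshold + margin`. A pure translation moves every atom by the same
#' distance, so the in-place substructure RMSD of each pose equals its
#' translation norm analytically -- the planted `k` is exact by
#' construction.
#'
#' @param reference A [mol3d()] containing the anchoring pattern.
#' @param N Total poses (default 50: 25 saved poses for each of 2 receptors).
#' @param k Poses below the threshold.
#' @param threshold RMSD threshold (default 2 Angstrom).
#' @param margin Clearance above the threshold for non-matching poses.
#' @param seed Integer seed.
#' @return List with `poses` (list of [mol3d()]), `scores` (synthetic,
#'   higher-better), `k`, `N`, `threshold`.
#' @export
gen_pose_set <- function(reference, N = 50, k = 8, threshold = 2,
                         margin = 1, seed = 1) {
  stopifnot(k >= 0, k <= N)
  with_seed(seed, {
    dists <- c(runif(k, 0.05, 0.9 * threshold),
               threshold + margin + runif(N - k, 0, 4))
    ord <- sample.int(N)
    dists <- dists[ord]
    is_match <- c(rep(TRUE, k), rep(FALSE, N - k))[ord]
    poses <- lapply(seq_len(N), function(i) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      m <- reference
      m$xyz <- sweep(m$xyz, 2, dists[i] * dir, "+")
      m$name <- sprintf("pose%02d", i)
      m
    })
    scores <- ifelse(is_match, 60, 40) + runif(N, 0, 5)
    list(poses = poses, scores = scores, k = k, N = N,
         threshold = threshold, true_match = is_match)
  })
}

# Idealized alpha-helix backbone (N, CA, C, O per residue).
ideal_helix <- function(n_res, resids = NULL, origin = c(0, 0, 0)) {
  if (is.null(resids)) resids <- rep("ALA", n_res)
  stopifnot(length(resids) == n_res)
  rows <- list()
  for (i in seq_len(n_res)) {
    phi <- (i - 1) * 100 * pi / 180
    z <- (i - 1) * 1.5
    ca <- c(2.3 * cos(phi), 2.3 * sin(phi), z) + origin
    offs <- list(N = c(-0.8, -0.9, -0.6), CA = c(0, 0, 0),
                 C = c(0.9, 0.6, 0.6), O = c(1.1, 1.6, 0.4))
    rot <- matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
    for (nm in names(offs)) {
      p <- ca + as.numeric(rot %*% offs[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        element = substr(nm, 1, 1), name = nm, resno = i,
        resid = resids[i], segment = "protein", water_id = NA_integer_,
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Simple rigid ligand atom set (aromatic-ish ring + amine N + hydroxyl O)
# centred at `center`.
toy_ligand <- function(center) {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  xyz <- rbind(ring, c(2.8, 0, 0.4), c(-2.6, 0.6, -0.4))
  xyz <- sweep(xyz, 2, center, "+")
  data.frame(element = c(rep("C", 6), "N", "O"),
             name = c(paste0("C", 1:6), "N1", "O1"),
             resno = 900L, resid = "LIG", segment = "ligand",
             water_id = NA_integer_,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a toy MD trajectory
#'
#' A rigid idealized helix (optionally jittered), a ligand that either
#' stays in the pocket or departs at a planned frame, and waters random-
#' walking in a periodic box. Ground truth (pocket residues, planned
#' departure frame, per-frame waters placed inside the monitoring sphere)
#' is attached as attributes.
#'
#' @param n_frames Number of frames.
#' @param n_waters Number of water molecules (oxygen sites).
#' @param ligand `"resident"`, `"escape"` or `"none"`.
#' @param escape_frame Planned first departed frame (escape mode).
#' @param n_inside Waters pinned inside the 6-Angstrom pocket sphere each
#'   frame (the rest stay outside).
#' @param box Periodic box edges (Angstrom).
#' @param jitter Protein per-coordinate jitter SD (0 = rigid).
#' @param stride_ps Frame spacing (ps).
#' @param seed Integer seed.
#' @return A [trajectory()] with attributes `pocket_residues`,
#'   `escape_frame`, `n_inside`.
#' @export
gen_trajectory <- function(n_frames = 100, n_waters = 30,
                           ligand = c("resident", "escape", "none"),
                           escape_frame = 50, n_inside = 5,
                           box = c(40, 40, 40), jitter = 0,
                           stride_ps = 10, seed = 1) {
  ligand <- match.arg(ligand)
  stopifnot(n_frames >= 2, n_inside <= n_waters)
  n_res <- 20
  prot <- ideal_helix(n_res)
  prot[, c("x", "y", "z")] <- prot[, c("x", "y", "z")] +
    matrix(rep(box / 2 - c(0, 0, 15), each = nrow(prot)), ncol = 3)
  pocket_res <- 8:12
  pocket_ca <- prot[prot$name == "CA" & prot$resno %in% pocket_res, ]
  pocket_ctr <- colMeans(as.matrix(pocket_ca[, c("x", "y", "z")])) + c(4, 0, 0)
  top <- prot
  if (ligand != "none") {
    top <- rbind(top, toy_ligand(pocket_ctr))
  }
  if (n_waters > 0) {
    wxyz <- with_seed(seed + 1, {
      inside <- matrix(rnorm(3 * n_inside, sd = 1.5), ncol = 3)
      inside <- sweep(inside, 1, pmin(sqrt(rowSums(inside^2)), 4.5) /
                        pmax(sqrt(rowSums(inside^2)), 1e-9), "*")
      inside <- sweep(inside, 2, pocket_ctr, "+")
      outside <- matrix(runif(3 * (n_waters - n_inside)), ncol = 3)
      outside <- sweep(outside, 2, box, "*")
      d <- min_image_dist(outside, pocket_ctr, box)
      # push any accidental in-sphere water out along x
      bad <- d <= 10
      outside[bad, 1] <- pocket_ctr[1] + 15
      rbind(inside, outside)
    })
    waters <- data.frame(element = "O", name = "OW",
                         resno = 1000L + seq_len(n_waters), resid = "HOH",
                         segment = "water", water_id = seq_len(n_waters),
                         x = wxyz[, 1], y = wxyz[, 2], z = wxyz[, 3],
                         stringsAsFactors = FALSE)
    top <- rbind(top, waters)
  }
  base <- unname(as.matrix(top[, c("x", "y", "z")]))
  topo <- top[, c("element", "name", "resno", "resid", "segment", "water_id")]
  lig_idx <- which(topo$segment == "ligand")
  wat_idx <- which(topo$segment == "water")
  prot_idx <- which(topo$segment == "protein")
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    x <- base
    if (jitter > 0) {
      x[prot_idx, ] <- x[prot_idx, ] +
        matrix(rnorm(3 * length(prot_idx), sd = jitter),
               ncol = 3)
    }
    if (length(wat_idx) > n_inside) {
      drift <- matrix(rnorm(3 * (length(wat_idx) - n_inside), sd = 0.3),
                      ncol = 3) * f
      out_rows <- if (n_inside > 0) wat_idx[-seq_len(n_inside)] else wat_idx
      x[out_rows, ] <- sweep((x[out_rows, ] + drift), 2, box, "%%")
      # outside waters must stay outside the monitored sphere: relocate any
      # drifter that wandered within clearance of the pocket
      d <- min_image_dist(x[out_rows, , drop = FALSE], pocket_ctr, box)
      bad <- d <= 8
      if (any(bad)) {
        x[out_rows[bad], ] <- matrix(rep(
          (pocket_ctr + c(15, 0, 0)) %% box, sum(bad)),
          ncol = 3, byrow = TRUE)
      }
    }
    if (length(lig_idx) && ligand == "escape" && f >= escape_frame) {
      x[lig_idx, ] <- sweep(x[lig_idx, ], 2,
                            c(12 + 0.2 * (f - escape_frame), 0, 0), "+")
    }
    x
  }))
  out <- trajectory(topo, frames, box = box, stride_ps = stride_ps)
  attr(out, "pocket_residues") <- pocket_res
  attr(out, "escape_frame") <- if (ligand == "escape") escape_frame else NA
  attr(out, "n_inside") <- n_inside
  out
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  if (!is.null(traj$box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       traj$box[1], traj$box[2], traj$box[3]), con)
  }
  chain <- ifelse(top$segment == "protein", "A",
                  ifelse(top$segment == "ligand", "B", "W"))
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- traj$frames[[f]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(top)), substr(top$name, 1, 4), substr(top$resid, 1, 3),
      chain, top$resno, x[, 1], x[, 2], x[, 3], top$element), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Generate per-frame energy tables with exact per-residue partition
#'
#' Component columns are i.i.d. normal around the planned means; optional
#' per-residue columns partition each frame's total exactly via fixed
#' random weights.
#'
#' @param n_frames Number of frames.
#' @param means Named vector over `dE_MM`, `dG_polar`, `dG_nonpolar`
#'   (kcal/mol).
#' @param sds Matching SDs.
#' @param residues Residue numbers for the decomposition (NULL for none).
#' @param seed Integer seed.
#' @return An `energy_frames` data frame with attribute `true_means`.
#' @export
gen_energy_tables <- function(n_frames = 200,
                              means = c(dE_MM = -40, dG_polar = 25,
                                        dG_nonpolar = -4),
                              sds = c(dE_MM = 3, dG_polar = 2,
                                      dG_nonpolar = 0.5),
                              residues = NULL, seed = 1) {
  stopifnot(all(ENERGY_COMPONENTS %in% names(means)),
            all(ENERGY_COMPONENTS %in% names(sds)))
  df <- with_seed(seed, {
    out <- data.frame(frame = seq_len(n_frames))
    for (k in ENERGY_COMPONENTS) {
      out[[k]] <- rnorm(n_frames, means[[k]], sds[[k]])
    }
    if (!is.null(residues)) {
      w <- runif(length(residues), 0.2, 1)
      w <- w / sum(w)
      total <- rowSums(out[, ENERGY_COMPONENTS])
      for (j in seq_along(residues)) {
        out[[paste0("res_", residues[j])]] <- total * w[j]
      }
    }
    out
  })
  class(df) <- c("energy_frames", "data.frame")
  attr(df, "true_means") <- means
  df
}

#' Generate a homologous sequence pair with planted divergence
#'
#' A random amino-acid sequence and a copy with a planted fraction of
#' substituted positions (no indels): the recovered global-alignment
#' identity equals the planted identity, giving the aligner an exact
#' parameter-recovery oracle.
#'
#' @param length Sequence length (default 160, an HA-binding-domain-sized
#'   chain).
#' @param identity Target fractional identity (default 0.87).
#' @param seed Integer seed.
#' @return List: `a`, `b` (strings), `planted_identity` (the exact planted
#'   fraction).
#' @export
gen_homolog_sequences <- function(length = 160, identity = 0.87, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    s <- sample(aa, length, replace = TRUE)
    n_mut <- round((1 - identity) * length)
    pos <- sample.int(length, n_mut)
    t <- s
    for (p in pos) t[p] <- sample(setdiff(aa, s[p]), 1)
    list(a = paste(s, collapse = ""), b = paste(t, collapse = ""),
         planted_identity = 1 - n_mut / length)
  })
}

#' Build a structure model from a toy helix
#'
#' @param n_res Residue count.
#' @param resids Residue names (default all ALA).
#' @param displace Optional list `list(resno =, by =)` rigidly displacing
#'   one residue's atoms (for profile spike fixtures).
#' @return A `structure_model`.
#' @export
gen_toy_structure <- function(n_res = 20, resids = NULL, displace = NULL) {
  at <- ideal_helix(n_res, resids)
  if (!is.null(displace)) {
    sel <- at$resno == displace$resno
    at[sel, c("x", "y", "z")] <- sweep(as.matrix(at[sel, c("x", "y", "z")]),
                                       2, displace$by, "+")
  }
  atoms <- data.frame(resno = at$resno, resid = at$resid, elety = at$name,
                      element = at$element, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  seq1 <- vapply(unique(at$resno), function(r) {
    bio3d::aa321(at$resid[at$resno == r][1])
  }, character(1))
  structure(list(atoms = atoms, sequence = paste(seq1, collapse = ""),
                 resnos = unique(at$resno), chain = "A", source = "synthetic"),
            class = "structure_model")
}
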