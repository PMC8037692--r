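# MD-trajectory post-analysis. Trajectories are frames x atoms coordinate
# stacks with a labelled topology (protein residues, ligand, waters) and an
# optional periodic box. The MD engine is upstream: inputs are multi-model
# PDB (or DCD via bio3d) files, or synthetic fixtures.

#' Construct a trajectory object
#'
#' @param topology Data frame with one row per atom: `element`, `name`
#'   (atom name), `resno`, `resid`, `segment` (one of `"protein"`,
#'   `"ligand"`, `"water"`), `water_id` (molecule id for waters, else `NA`).
#' @param frames List of n_atoms x 3 coordinate matrices (Angstrom).
#' @param box Length-3 periodic box, or `NULL`.
#' @param stride_ps Time between frames (ps).
#' @return A `trajectory` object.
#' @export
trajectory <- function(topology, frames, box = NULL, stride_ps = 10) {
  need <- c("element", "name", "resno", "resid", "segment", "water_id")
  stopifnot(all(need %in% names(topology)), length(frames) >= 1,
            stride_ps > 0)
  n <- nrow(topology)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n &&
                 ncol(f) == 3, logical(1))
  if (!all(ok)) stop("every frame must be an n_atoms x 3 matrix", call. = FALSE)
  structure(list(topology = topology, frames = frames, box = box,
                 stride_ps = stride_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  seg <- table(x$topology$segment)
  cat("trajectory:", length(x$frames), "frames x", nrow(x$topology),
      "atoms (", paste(sprintf("%s: %d", names(seg), seg), collapse = ", "),
      ")", if (!is.null(x$box)) paste0("box ", paste(round(x$box, 1),
                                                     collapse = " x ")), "\n")
  invisible(x)
}

#' Read a multi-model PDB trajectory
#'
#' Model 1 supplies the topology; waters are recognized by residue name
#' (HOH/WAT/SOL/TIP3), the ligand by `ligand_resid`, everything else is
#' protein.
#'
#' @param path Multi-model PDB file.
#' @param ligand_resid Residue name of the ligand (default `"LIG"`).
#' @param box Length-3 periodic box (read from CRYST1 when present).
#' @param stride_ps Frame spacing in ps.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path, ligand_resid = "LIG", box = NULL,
                                stride_ps = 10) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  water_names <- c("HOH", "WAT", "SOL", "TIP3", "TIP")
  segment <- ifelse(at$resid %in% water_names, "water",
                    ifelse(at$resid == ligand_resid, "ligand", "protein"))
  water_id <- ifelse(segment == "water", at$resno, NA_integer_)
  topology <- data.frame(element = at$elesy, name = at$elety,
                         resno = at$resno, resid = at$resid,
                         segment = segment, water_id = water_id,
                         stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  if (is.null(box)) {
    cl <- grep("^CRYST1", readLines(path, n = 50), value = TRUE)
    if (length(cl)) {
      abc <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                          substr(cl[1], 25, 33)))
      if (all(is.finite(abc)) && all(abc > 0)) box <- abc
    }
  }
  trajectory(topology, frames, box = box, stride_ps = stride_ps)
}

# Atom index helpers ---------------------------------------------------------

sel_backbone <- function(top) {
  which(top$segment == "protein" & top$name %in% c("N", "CA", "C", "O"))
}
sel_ca <- function(top) which(top$segment == "protein" & top$name == "CA")
sel_water_o <- function(top) {
  which(top$segment == "water" & top$element == "O")
}
sel_ligand_heavy <- function(top) {
  which(top$segment == "ligand" & top$element != "H")
}

resolve_selection <- function(traj, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  switch(selection,
         backbone = sel_backbone(traj$topology),
         ca = sel_ca(traj$topology),
         protein = which(traj$topology$segment == "protein"),
         ligand = sel_ligand_heavy(traj$topology),
         stop("unknown selection: ", selection, call. = FALSE))
}

#' Per-frame RMSD series
#'
#' Each frame is superposed onto the reference over the selection (Kabsch)
#' before the deviation is computed.
#'
#' @param traj A [trajectory()].
#' @param reference Reference coordinates for the full atom set (defaults to
#'   the first frame).
#' @param selection `"backbone"` (default), `"ca"`, `"protein"`, `"ligand"`
#'   or an integer atom index vector.
#' @param superpose Fit each frame onto the reference first (default TRUE);
#'   `FALSE` gives the raw in-frame deviation.
#' @return Numeric vector of per-frame RMSD (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, selection = "backbone",
                        superpose = TRUE) {
  idx <- resolve_selection(traj, selection)
  if (length(idx) == 0) stop("empty selection", call. = FALSE)
  ref <- if (is.null(reference)) traj$frames[[1]] else reference
  if (nrow(ref) != nrow(traj$topology)) {
    stop("reference atom count mismatch", call. = FALSE)
  }
  ref_sel <- ref[idx, , drop = FALSE]
  vapply(traj$frames, function(f) {
    rmsd_coords(f[idx, , drop = FALSE], ref_sel, superpose = superpose)
  }, numeric(1))
}

#' Per-residue RMSF profile
#'
#' Frames are aligned to the mean structure (two refinement passes), then
#' the fluctuation of each residue's selected atoms about their time-mean
#' positions is reported.
#'
#' @param traj A [trajectory()].
#' @param selection `"ca"` (default), `"backbone"`, or an atom index vector.
#' @return Named numeric vector: RMSF (Angstrom) per residue number.
#' @export
rmsf_profile <- function(traj, selection = "ca") {
  if (length(traj$frames) < 2) stop("need at least 2 frames", call. = FALSE)
  idx <- resolve_selection(traj, selection)
  if (length(idx) == 0) stop("empty selection", call. = FALSE)
  stack <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  ref <- stack[[1]]
  for (pass in 1:2) {
    aligned <- lapply(stack, function(x) kabsch(x, ref)$transform(x))
    ref <- Reduce(`+`, aligned) / length(aligned)
  }
  mean_xyz <- ref
  dev2 <- Reduce(`+`, lapply(aligned, function(x) {
    rowSums((x - mean_xyz)^2)
  })) / length(aligned)
  resno <- traj$topology$resno[idx]
  out <- vapply(split(dev2, resno), function(v) sqrt(mean(v)), numeric(1))
  out[order(as.integer(names(out)))]
}

# Per-frame sphere centre from a centre spec: fixed point (length-3 numeric)
# or residue numbers whose CA centroid is recomputed every frame.
sphere_center <- function(traj, center_spec, frame_xyz) {
  if (is.numeric(center_spec) && length(center_spec) == 3 &&
      is.null(attr(center_spec, "residues"))) {
    return(as.numeric(center_spec))
  }
  res <- if (!is.null(attr(center_spec, "residues"))) {
    attr(center_spec, "residues")
  } else center_spec
  idx <- which(traj$topology$segment == "protein" &
                 traj$topology$name == "CA" &
                 traj$topology$resno %in% res)
  if (length(idx) == 0) stop("no CA atoms for the centre residues",
                             call. = FALSE)
  colMeans(frame_xyz[idx, , drop = FALSE])
}

#' Pocket residue centre specification
#'
#' Marks a residue-number vector as a tracked sphere centre (the per-frame
#' centroid of those residues' CA atoms).
#'
#' @param residues Integer residue numbers lining the pocket.
#' @return A centre spec for [water_occupancy()] / [ligand_residency()].
#' @export
pocket_center <- function(residues) {
  structure(numeric(0), residues = as.integer(residues))
}

#' Binding-site water occupancy
#'
#' Counts water oxygens within `radius` of the sphere centre in every frame
#' (minimum-image distances when the trajectory has a box; the boundary is
#' inclusive).
#'
#' @param traj A [trajectory()].
#' @param center_spec Fixed point (xyz) or [pocket_center()] residue spec.
#' @param radius Sphere radius in Angstrom (default 6, the binding-pocket
#'   monitoring radius).
#' @return Integer vector: water count per frame.
#' @export
water_occupancy <- function(traj, center_spec, radius = 6) {
  wo <- sel_water_o(traj$topology)
  if (length(wo) == 0) {
    warning("trajectory contains no waters; occupancy is identically zero",
            call. = FALSE)
    return(rep(0L, length(traj$frames)))
  }
  vapply(traj$frames, function(f) {
    ctr <- sphere_center(traj, center_spec, f)
    d <- min_image_dist(f[wo, , drop = FALSE], ctr, traj$box)
    sum(d <= radius)
  }, integer(1))
}

#' Ligand residency in a binding pocket
#'
#' The ligand is departed when its heavy-atom centroid stays beyond
#' `radius` from the pocket centre for at least `persistence` consecutive
#' frames; the departure frame is the first frame of that run. Transient
#' excursions shorter than the persistence window do not count.
#'
#' @param traj A [trajectory()].
#' @param center_spec Fixed point or [pocket_center()] spec.
#' @param radius Pocket radius (Angstrom).
#' @param persistence Consecutive-frame window (default 10).
#' @return List: `status` (`"resident"` or `"departed"`), `departure_frame`
#'   (`NA` if resident), `distances` (per-frame centroid distance).
#' @export
ligand_residency <- function(traj, center_spec, radius = 6,
                             persistence = 10) {
  lig <- sel_ligand_heavy(traj$topology)
  if (length(lig) == 0) stop("trajectory has no ligand atoms", call. = FALSE)
  d <- vapply(traj$frames, function(f) {
    ctr <- sphere_center(traj, center_spec, f)
    cen <- colMeans(f[lig, , drop = FALSE])
    sqrt(sum(min_image_delta(cen - ctr, traj$box)^2))
  }, numeric(1))
  out <- d > radius
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit)) {
    list(status = "departed", departure_frame = starts[hit[1]], distances = d)
  } else {
    list(status = "resident", departure_frame = NA_integer_, distances = d)
  }
}

min_image_delta <- function(v, box) {
  if (is.null(box)) return(v)
  v - box * round(v / box)
}
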