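# Docking-pose post-analysis: substructure-anchored RMSD, redocking
# validation, match-frequency statistics, pocket-selectivity ranking and
# pose clustering. Docking engines are upstream; poses arrive as SDF/PDB
# coordinate sets sharing the receptor frame.

#' Substructure-anchored in-place RMSD
#'
#' Finds every embedding of `pattern` in both structures (element-colored
#' subgraph isomorphism, including ring automorphisms) and returns the
#' minimum in-place heavy-atom RMSD over all mapping pairs. No
#' re-superposition is performed: both structures are assumed to share the
#' receptor/crystal frame.
#'
#' @param pose,reference [mol3d()] objects in a common frame.
#' @param pattern Pattern graph (e.g. [thq_pattern()]), a SMILES string, or
#'   `NULL` to map the full heavy-atom graph of `reference`.
#' @param superpose If `TRUE`, Kabsch-fit the mapped atoms first (off by
#'   default, the crystallographic convention).
#' @return A `substructure_rmsd` list: `rmsd`, `mapping` (pose indices),
#'   `ref_mapping`, `n_atoms`.
#' @export
substructure_rmsd <- function(pose, reference, pattern = NULL,
                              superpose = FALSE) {
  pat <- resolve_pattern(pattern, reference)
  g_pose <- strip_h_graph(pose)
  g_ref <- strip_h_graph(reference)
  maps_pose <- match_pattern(g_pose$graph, pat)
  if (length(maps_pose) == 0) {
    stop("pattern absent in pose structure", call. = FALSE)
  }
  maps_ref <- match_pattern(g_ref$graph, pat)
  if (length(maps_ref) == 0) {
    stop("pattern absent in reference structure", call. = FALSE)
  }
  best <- list(rmsd = Inf)
  for (mr in maps_ref) {
    ref_xyz <- reference$xyz[g_ref$atoms[mr], , drop = FALSE]
    for (mp in maps_pose) {
      pose_xyz <- pose$xyz[g_pose$atoms[mp], , drop = FALSE]
      r <- rmsd_coords(pose_xyz, ref_xyz, superpose = superpose)
      if (r < best$rmsd) {
        best <- list(rmsd = r, mapping = g_pose$atoms[mp],
                     ref_mapping = g_ref$atoms[mr],
                     n_atoms = length(mp))
      }
    }
  }
  structure(best, class = "substructure_rmsd")
}

resolve_pattern <- function(pattern, reference) {
  if (is.null(pattern)) {
    g <- strip_h_graph(reference)$graph
    return(g)
  }
  if (is.character(pattern)) return(mol_graph(pattern))
  pattern
}

# Heavy-atom graph + original atom indices of a mol3d.
strip_h_graph <- function(mol) {
  keep <- heavy_atoms(mol)
  idx <- match(seq_along(mol$elements), keep)
  bonds <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, ]
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  g <- igraph::add_edges(g, rbind(idx[bonds$a1], idx[bonds$a2]))
  el <- mol$elements[keep]
  igraph::V(g)$element <- el
  igraph::V(g)$color <- element_code(el)
  igraph::E(g)$order <- bonds$order
  list(graph = g, atoms = keep)
}

#' Redocking validation against a crystal pose
#'
#' @param poses List of [mol3d()] poses (same chemistry as the crystal
#'   ligand, same frame).
#' @param crystal The crystallographic ligand ([mol3d()]).
#' @param threshold All-heavy-atom in-place RMSD below which the binding
#'   mode counts as reproduced (default 3 Angstrom).
#' @return List: `success`, `best_rmsd`, `best_pose`, `rmsds`.
#' @export
redock_validation <- function(poses, crystal, threshold = 3) {
  stopifnot(length(poses) >= 1)
  n_ref <- length(heavy_atoms(crystal))
  rmsds <- vapply(poses, function(p) {
    if (length(heavy_atoms(p)) != n_ref) {
      stop("atom-count mismatch between pose and crystal ligand", call. = FALSE)
    }
    substructure_rmsd(p, crystal, pattern = NULL)$rmsd
  }, numeric(1))
  best <- which.min(rmsds)
  list(success = rmsds[best] < threshold, best_rmsd = rmsds[best],
       best_pose = best, rmsds = rmsds)
}

#' Frequency of reference-matching poses across receptors
#'
#' Counts poses whose substructure-anchored RMSD to the crystal reference is
#' below `threshold`, pooled over all supplied pose sets (e.g. 25 poses for
#' each of two receptors giving a /50 denominator).
#'
#' @param pose_sets List of lists of [mol3d()] poses (one list per receptor),
#'   or a single flat list of poses.
#' @param reference Crystal reference structure ([mol3d()]).
#' @param pattern Anchoring pattern (default the THQ core).
#' @param threshold RMSD threshold in Angstrom (default 2).
#' @return List: `k` (matching poses), `n` (total poses), `fraction`, and
#'   `label` (the exact `k/n` string).
#' @export
match_frequency <- function(pose_sets, reference, pattern = thq_pattern(),
                            threshold = 2) {
  if (length(pose_sets) && inherits(pose_sets[[1]], "mol3d")) {
    pose_sets <- list(pose_sets)
  }
  poses <- unlist(pose_sets, recursive = FALSE)
  if (length(poses) == 0) stop("empty pose sets", call. = FALSE)
  rmsds <- vapply(poses, function(p) {
    substructure_rmsd(p, reference, pattern = pattern)$rmsd
  }, numeric(1))
  k <- sum(rmsds < threshold)
  n <- length(poses)
  list(k = k, n = n, fraction = k / n, label = paste0(k, "/", n),
       rmsds = rmsds)
}

#' Pocket-selectivity ranking of docking scores
#'
#' Ranks pockets by each pocket's best score and flags candidates whose
#' preferred pocket is not the target. The score convention (higher- or
#' lower-is-better) must be declared, never guessed. Ties with the target's
#' best score count as "similar affinity" and are not flagged.
#'
#' @param scores Data frame with columns `pocket` and `score` (one row per
#'   saved pose or per pocket-best).
#' @param target_pocket Pocket id of the region of interest.
#' @param convention `"higher_better"` or `"lower_better"`.
#' @param tie_tol Absolute score difference treated as a tie.
#' @return List: `ranking` (data frame pocket/best/rank), `target_rank`,
#'   `flagged` (TRUE when another pocket strictly outranks the target).
#' @export
pocket_selectivity <- function(scores, target_pocket,
                               convention = c("higher_better", "lower_better"),
                               tie_tol = 1e-8) {
  convention <- match.arg(convention)
  stopifnot(all(c("pocket", "score") %in% names(scores)))
  if (!target_pocket %in% scores$pocket) {
    stop("target pocket '", target_pocket, "' absent from score table",
         call. = FALSE)
  }
  if (length(unique(scores$pocket)) < 2) {
    stop("need at least two pockets", call. = FALSE)
  }
  best <- aggregate(score ~ pocket, data = scores,
                    FUN = if (convention == "higher_better") max else min)
  ord <- if (convention == "higher_better") -best$score else best$score
  # ties share the top rank
  best$rank <- rank(ord, ties.method = "min")
  best <- best[order(best$rank), , drop = FALSE]
  rownames(best) <- NULL
  t_best <- best$score[best$pocket == target_pocket]
  top <- best$score[best$rank == 1][1]
  tied_top <- abs(t_best - top) <= tie_tol
  list(ranking = best,
       target_rank = best$rank[best$pocket == target_pocket],
       flagged = !(best$rank[best$pocket == target_pocket] == 1 || tied_top))
}

#' Hierarchical pose clustering
#'
#' Agglomerative clustering of poses on pairwise RMSD (substructure-anchored
#' or all-heavy-atom), cut at a distance cutoff; each cluster is represented
#' by its best-scored member (for downstream MD seeding).
#'
#' @param poses List of [mol3d()] poses.
#' @param scores Optional numeric vector of docking scores (same length).
#' @param pattern Pattern for the pairwise RMSD, or `NULL` for all heavy
#'   atoms.
#' @param linkage `hclust` method (default `"complete"`).
#' @param cutoff Cluster cut height in Angstrom.
#' @param convention Score convention for representative selection.
#' @return List: `clusters` (integer labels), `representatives` (pose index
#'   per cluster), `n_clusters`, `distance` (matrix).
#' @export
cluster_poses <- function(poses, scores = NULL, pattern = NULL,
                          linkage = "complete", cutoff = 2,
                          convention = c("higher_better", "lower_better")) {
  convention <- match.arg(convention)
  n <- length(poses)
  if (n < 2) stop("need at least two poses", call. = FALSE)
  if (is.null(scores)) scores <- rep(0, n)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <-
        substructure_rmsd(poses[[i]], poses[[j]], pattern = pattern)$rmsd
    }
  }
  labels <- if (all(D < .Machine$double.eps)) rep(1L, n) else
    cutree(hclust(as.dist(D), method = linkage), h = cutoff)
  reps <- vapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    sc <- scores[members]
    members[if (convention == "higher_better") which.max(sc) else which.min(sc)]
  }, integer(1))
  list(clusters = labels, representatives = reps,
       n_clusters = length(unique(labels)), distance = D)
}

#' Read a docking score table
#'
#' CSV with columns `ligand`, `receptor`, `pocket`, `pose_index`, `score`
#' and a header-declared convention: the file's first line may be a comment
#' `# convention: higher_better` (or `lower_better`); alternatively pass it
#' explicitly.
#'
#' @param path CSV path.
#' @param convention Override when the file has no declaration.
#' @return Data frame with attribute `convention`.
#' @export
read_score_table <- function(path, convention = NULL) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("#\\s*convention:\\s*(\\S+)", first))[[1]]
  if (length(m) == 2) {
    convention <- m[2]
  }
  if (is.null(convention)) {
    stop("score convention not declared (no '# convention:' header and no ",
         "explicit argument)", call. = FALSE)
  }
  convention <- match.arg(convention, c("higher_better", "lower_better"))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "convention") <- convention
  df
}
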