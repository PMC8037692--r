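# Ensemble pharmacophore modeling and screening.
#
# Features are typed points in the receptor frame: aromatic ring centroids,
# hydrogen-bond donors/acceptors at the heavy atom, protonatable amines
# (positive ionizable at physiological pH), carboxylate-type negative
# centres, and all-carbon ring centroids as hydrophobic points. The ensemble
# model merges same-kind features that agree across aligned ligands and
# records per-feature support.

FEATURE_KINDS <- c("aromatic", "hbd", "hba", "pos_ion", "neg_ion",
                   "hydrophobic")

#' Perceive typed pharmacophore features of a 3D molecule
#'
#' Rules (at the default pH 7.4): `aromatic` = centroid of each aromatic
#' ring; `hbd` = each N/O carrying at least one hydrogen; `hba` = each
#' oxygen and each non-protonated, non-amide, lone-pair-bearing nitrogen;
#' `pos_ion` = aliphatic (non-amide, non-aryl) amine nitrogens, protonated
#' at this pH, plus formally charged cations; `neg_ion` = carboxylic-acid
#' carbons (deprotonated at this pH); `hydrophobic` = centroid of each
#' all-carbon ring.
#'
#' @param mol A [mol3d()] (explicit hydrogens welcome; implicit hydrogens
#'   are inferred from valence otherwise).
#' @param pH Protonation reference, informational (rules are fixed for the
#'   physiological window around 7.4).
#' @return A `pharm_features` data frame: `kind`, `x`, `y`, `z`, `atoms`
#'   (list column of provenance atom indices).
#' @export
perceive_features <- function(mol, pH = 7.4) {
  g <- mol3d_graph(mol)
  el <- mol$elements
  xyz <- mol$xyz
  expl_h <- vapply(seq_along(el), function(v) {
    sum(el[as.integer(igraph::neighbors(g, v))] == "H")
  }, integer(1))
  h_tot <- expl_h + implicit_hydrogens(g)
  arom <- aromatic_atoms(g)
  rings <- find_rings(g)
  feats <- list()
  add <- function(kind, center, atoms) {
    feats[[length(feats) + 1L]] <<- data.frame(
      kind = kind, x = center[1], y = center[2], z = center[3],
      atoms = I(list(atoms)))
  }
  for (ring in rings) {
    center <- colMeans(xyz[ring, , drop = FALSE])
    if (all(arom[ring])) add("aromatic", center, ring)
    if (all(el[ring] == "C")) add("hydrophobic", center, ring)
  }
  heavy_nb <- function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    nb[el[nb] != "H"]
  }
  is_amide_n <- function(v) {
    any(vapply(heavy_nb(v), function(c_at) {
      el[c_at] == "C" && is_amide_bond(g, el, c_at, v)
    }, logical(1)))
  }
  for (v in which(el %in% c("N", "O"))) {
    bsum <- sum(igraph::E(g)$order[as.integer(igraph::incident(g, v))]) +
      implicit_hydrogens(g)[v]
    if (h_tot[v] > 0) add("hbd", xyz[v, ], v)
    if (el[v] == "O") {
      add("hba", xyz[v, ], v)
    } else {
      aryl <- any(arom[heavy_nb(v)])
      if (!arom[v] && !is_amide_n(v) && bsum <= 3) {
        if (!aryl) {
          # aliphatic amine: protonated, positive ionizable (also a donor
          # once protonated)
          add("pos_ion", xyz[v, ], v)
          if (h_tot[v] == 0) add("hbd", xyz[v, ], v)
        } else {
          add("hba", xyz[v, ], v)
        }
      } else if (arom[v] && h_tot[v] == 0) {
        add("hba", xyz[v, ], v)   # pyridine-type nitrogen
      }
    }
  }
  for (c_at in which(el == "C")) {
    nb <- heavy_nb(c_at)
    os <- nb[el[nb] == "O"]
    if (length(os) == 2) {
      has_dbl <- any(vapply(os, function(o) {
        igraph::E(g)$order[igraph::get_edge_ids(g, c(c_at, o))] == 2
      }, logical(1)))
      oh <- any(h_tot[os] > 0)
      if (has_dbl && oh) add("neg_ion", colMeans(xyz[c(c_at, os), ]), c(c_at, os))
    }
  }
  out <- if (length(feats)) do.call(rbind, feats) else
    data.frame(kind = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), atoms = I(list()))
  class(out) <- c("pharm_features", "data.frame")
  out
}

# Small-ring inventory (chordless cycles up to 7 atoms): shortest cycle
# through each non-bridge edge.
find_rings <- function(g) {
  ring_eids <- setdiff(seq_len(igraph::ecount(g)),
                       as.integer(igraph::bridges(g)))
  rings <- list()
  seen <- character(0)
  for (eid in ring_eids) {
    ends <- as.integer(igraph::ends(g, eid, names = FALSE))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(g2, ends[1], ends[2]))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) < 3 || length(path) > 7) next
    key <- paste(sort(path), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- path
  }
  rings
}

#' Build an ensemble consensus pharmacophore
#'
#' Pools same-kind features across pre-aligned ligands, merges features that
#' agree to within `consensus_radius` (complete-linkage clustering) and
#' keeps clusters supported by at least `min_support` of the ensemble.
#'
#' @param ligands List of aligned [mol3d()] objects (or `pharm_features`).
#' @param keep_kinds Feature kinds admitted to the model.
#' @param consensus_radius Merge radius in Angstrom (default 0.5, the
#'   ensemble agreement threshold on the shared scaffold frame).
#' @param min_support Minimum fraction of ligands contributing (default 0.5).
#' @param frame Identifier of the shared coordinate frame.
#' @return A `pharmacophore_model`: features data frame (`kind`, `x`, `y`,
#'   `z`, `tolerance`, `support`, `n_ligands`), plus `frame`.
#' @export
build_ensemble_model <- function(ligands,
                                 keep_kinds = c("aromatic", "hbd", "pos_ion"),
                                 consensus_radius = 0.5, min_support = 0.5,
                                 frame = "ensemble") {
  if (length(keep_kinds) == 0) stop("keep_kinds must be non-empty", call. = FALSE)
  stopifnot(length(ligands) >= 1)
  keep_kinds <- match.arg(keep_kinds, FEATURE_KINDS, several.ok = TRUE)
  feats <- lapply(ligands, function(l) {
    f <- if (inherits(l, "pharm_features")) l else perceive_features(l)
    f[f$kind %in% keep_kinds, , drop = FALSE]
  })
  n_lig <- length(feats)
  pooled <- do.call(rbind, lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (nrow(f)) f$ligand <- i
    f
  }))
  rows <- list()
  for (kind in unique(pooled$kind)) {
    sub <- pooled[pooled$kind == kind, , drop = FALSE]
    cl <- if (nrow(sub) == 1) 1L else
      cutree(hclust(dist(sub[, c("x", "y", "z")]), method = "complete"),
             h = consensus_radius)
    for (cid in unique(cl)) {
      grp <- sub[cl == cid, , drop = FALSE]
      support <- length(unique(grp$ligand)) / n_lig
      if (support < min_support) next
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind,
        x = mean(grp$x), y = mean(grp$y), z = mean(grp$z),
        tolerance = consensus_radius, support = support)
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), tolerance = numeric(0), support = numeric(0))
  features <- features[order(features$kind, -features$support), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(features = features, frame = frame, n_ligands = n_lig,
                 consensus_radius = consensus_radius,
                 min_support = min_support),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("pharmacophore_model:", nrow(x$features), "features from",
      x$n_ligands, "ligand(s) [frame:", x$frame, "]\n")
  if (nrow(x$features)) {
    tab <- table(x$features$kind)
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Match a conformer against a pharmacophore model
#'
#' Every model feature must be paired with a distinct conformer feature of
#' the same kind; the reported RMSD is the minimum over all kind-respecting
#' one-to-one assignments. By default both objects are taken to share the
#' model frame (no re-alignment); `align = TRUE` additionally superposes the
#' conformer onto the model over the best feature correspondence.
#'
#' @param conformer A [mol3d()] or `pharm_features`.
#' @param model A `pharmacophore_model`.
#' @param rmsd_threshold Match threshold in Angstrom (default 0.5).
#' @param align Superpose on the feature correspondence before scoring.
#' @return List: `matched`, `rmsd`, `assignment` (data frame pairing model
#'   features with conformer feature rows), `reason` when unmatched.
#' @export
match_conformer <- function(conformer, model, rmsd_threshold = 0.5,
                            align = FALSE) {
  feats <- if (inherits(conformer, "pharm_features")) conformer else
    perceive_features(conformer)
  mf <- model$features
  if (nrow(mf) == 0) stop("empty pharmacophore model", call. = FALSE)
  for (kind in unique(mf$kind)) {
    need <- sum(mf$kind == kind)
    have <- sum(feats$kind == kind)
    if (have < need) {
      return(list(matched = FALSE, rmsd = Inf, assignment = NULL,
                  reason = paste0("conformer lacks required kind: ", kind,
                                  " (needs ", need, ", has ", have, ")")))
    }
  }
  res <- assign_features(mf, feats)
  if (align) {
    for (pass in 1:2) {
      mpts <- as.matrix(mf[res$model_row, c("x", "y", "z")])
      cpts <- as.matrix(feats[res$conf_row, c("x", "y", "z")])
      fit <- kabsch(cpts, mpts)
      feats[, c("x", "y", "z")] <- fit$transform(
        as.matrix(feats[, c("x", "y", "z")]))
      res <- assign_features(mf, feats)
    }
  }
  list(matched = res$rmsd < rmsd_threshold, rmsd = res$rmsd,
       assignment = data.frame(model_row = res$model_row,
                               conf_row = res$conf_row),
       reason = NULL)
}

# Optimal kind-respecting assignment: exhaustive within each kind (feature
# counts per kind are small).
assign_features <- function(mf, feats) {
  total_sq <- 0
  model_row <- integer(0); conf_row <- integer(0)
  for (kind in unique(mf$kind)) {
    mi <- which(mf$kind == kind)
    ci <- which(feats$kind == kind)
    cost <- matrix(0, length(mi), length(ci))
    for (a in seq_along(mi)) {
      d <- sweep(as.matrix(feats[ci, c("x", "y", "z")]), 2,
                 unlist(mf[mi[a], c("x", "y", "z")]))
      cost[a, ] <- rowSums(d^2)
    }
    sol <- best_assignment(cost)
    total_sq <- total_sq + sol$cost
    model_row <- c(model_row, mi)
    conf_row <- c(conf_row, ci[sol$cols])
  }
  list(rmsd = sqrt(total_sq / nrow(mf)), model_row = model_row,
       conf_row = conf_row)
}

#' Screen conformer sets against a pharmacophore model
#'
#' @param conformer_sets List of `conformer_set` objects (or lists of
#'   [mol3d()] per compound).
#' @param model A `pharmacophore_model`.
#' @param rmsd_threshold Match threshold (Angstrom).
#' @param align Passed to [match_conformer()].
#' @param receptor Optional [mol3d()]; conformers placing any heavy atom
#'   within `clash_cutoff` of a receptor heavy atom are rejected.
#' @param clash_cutoff Heavy-atom overlap cutoff (Angstrom).
#' @return A `screen_result`: `hits` data frame (compound, conformer, rmsd),
#'   `n_conformer_hits`, `n_compound_hits`, `n_screened`.
#' @export
screen_library <- function(conformer_sets, model, rmsd_threshold = 0.5,
                           align = FALSE, receptor = NULL,
                           clash_cutoff = 1.5) {
  rows <- list()
  n_screened <- 0L
  rec_xyz <- if (!is.null(receptor)) {
    receptor$xyz[heavy_atoms(receptor), , drop = FALSE]
  } else NULL
  for (cs in conformer_sets) {
    mols <- if (inherits(cs, "conformer_set")) cs$conformers else cs
    cmpd <- if (inherits(cs, "conformer_set")) cs$compound else
      mols[[1]]$name
    for (j in seq_along(mols)) {
      n_screened <- n_screened + 1L
      mol <- mols[[j]]
      if (!is.null(rec_xyz) && has_clash(mol, rec_xyz, clash_cutoff)) next
      m <- match_conformer(mol, model, rmsd_threshold, align = align)
      if (isTRUE(m$matched)) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cmpd, conformer = j, rmsd = m$rmsd)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound = character(0), conformer = integer(0),
               rmsd = numeric(0))
  structure(list(hits = hits,
                 n_conformer_hits = nrow(hits),
                 n_compound_hits = length(unique(hits$compound)),
                 n_screened = n_screened),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", x$n_conformer_hits, "conformer hits from",
      x$n_compound_hits, "unique compounds (", x$n_screened, "screened )\n")
  invisible(x)
}

has_clash <- function(mol, rec_xyz, cutoff) {
  lx <- mol$xyz[heavy_atoms(mol), , drop = FALSE]
  for (i in seq_len(nrow(lx))) {
    d2 <- rowSums(sweep(rec_xyz, 2, lx[i, ])^2)
    if (any(d2 < cutoff^2)) return(TRUE)
  }
  FALSE
}

#' Write a pharmacophore model to JSON
#'
#' @param model A `pharmacophore_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(model, path) {
  payload <- list(frame = model$frame, n_ligands = model$n_ligands,
                  consensus_radius = model$consensus_radius,
                  min_support = model$min_support,
                  features = model$features)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pharmacophore model from JSON
#'
#' @param path JSON file written by [write_pharmacophore()].
#' @return A `pharmacophore_model`.
#' @export
read_pharmacophore <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = as.data.frame(payload$features),
                 frame = payload$frame, n_ligands = payload$n_ligands,
                 consensus_radius = payload$consensus_radius,
                 min_support = payload$min_support),
            class = "pharmacophore_model")
}
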