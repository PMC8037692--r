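#' @importFrom methods new is
#' @importFrom stats aggregate as.dist cor cutree dist hclust kmeans na.omit
#'   prcomp rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv combn
NULL

# Empty option frame for ChemmineOB::convertFormat (its default forces gen2D,
# which is wasted work for string-to-string conversions).
ob_no_options <- function() data.frame(names = character(), args = character())

#' Locate the OpenBabel command-line binary
#'
#' The conformer engine shells out to `obabel`/`obenergy` for 3D embedding and
#' MMFF94 minimisation. All other OpenBabel functionality is reached in-process
#' through ChemmineOB.
#'
#' @param tool Binary name, `"obabel"` or `"obenergy"`.
#' @return Path to the binary.
#' @keywords internal
ob_binary <- function(tool = "obabel") {
  path <- Sys.which(tool)
  if (!nzchar(path)) {
    stop("OpenBabel tool '", tool, "' not found on PATH", call. = FALSE)
  }
  unname(path)
}

#' Canonicalize SMILES strings
#'
#' Batch canonicalization through OpenBabel. Stereochemistry is not written
#' (library deduplication is defined on the flat structure; the Ugi
#' stereocentre is left unspecified throughout).
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "C1CC1"))
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  stopifnot(is.character(smiles))
  ids <- paste0("m", seq_along(smiles))
  src <- paste(paste(smiles, ids), collapse = "\n")
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", source = src,
                              options = ob_no_options())
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  res <- rep(NA_character_, length(smiles))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smi <- vapply(parts, `[`, "", 1L)
    ttl <- trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""))
    idx <- match(ttl, ids)
    ok <- !is.na(idx)
    res[idx[ok]] <- trimws(smi[ok])
  }
  res
}

#' Count SMARTS matches per molecule
#'
#' @param smiles Character vector of SMILES.
#' @param smarts A single SMARTS pattern.
#' @param unique_matches Count symmetry-unique matches only.
#' @return Integer vector of match counts (`NA` for unparsable molecules).
#' @export
smarts_count <- function(smiles, smarts, unique_matches = TRUE) {
  stopifnot(is.character(smiles), length(smarts) == 1)
  res <- rep(NA_integer_, length(smiles))
  can <- canonical_smiles(smiles)
  ok <- which(!is.na(can))
  if (length(ok) == 0) return(res)
  src <- paste(can[ok], collapse = "\n")
  cnt <- tryCatch(
    ChemmineOB::forEachMol("SMI", src, function(m) {
      ChemmineOB::smartsSearch_OB(list(m), smarts,
                                  uniqueMatches = unique_matches)
    }),
    error = function(e) NULL
  )
  if (!is.null(cnt) && length(cnt) == length(ok)) {
    res[ok] <- as.integer(unlist(cnt))
  }
  res
}

#' Convert SMILES to SDF text via OpenBabel
#'
#' OpenBabel's own MDL writer is used so that formal charges travel as
#' `M  CHG` lines (round-trip safe; the old-style atom-line charge column is
#' not reliably honoured).
#'
#' @param smiles Named or unnamed character vector of SMILES.
#' @return A single string of concatenated molblocks.
#' @keywords internal
smiles_to_sdf_string <- function(smiles) {
  if (is.null(names(smiles))) names(smiles) <- paste0("m", seq_along(smiles))
  src <- paste(paste(smiles, names(smiles)), collapse = "\n")
  suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", source = src,
                              options = ob_no_options())
  )
}

#' Convert SMILES to an SDF set (connection tables)
#'
#' @param smiles Named or unnamed character vector of SMILES.
#' @return A `ChemmineR::SDFset`.
#' @keywords internal
smiles_to_sdfset <- function(smiles) {
  txt <- smiles_to_sdf_string(smiles)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  sdfset <- methods::as(ChemmineR::read.SDFstr(lines), "SDFset")
  if (length(sdfset) != length(smiles)) {
    stop("SMILES to SDF conversion dropped molecules", call. = FALSE)
  }
  sdfset
}

# Element symbol vector of an SDF instance (row names are like "C_1").
sdf_elements <- function(sdf) {
  sub("_.*$", "", rownames(ChemmineR::atomblock(sdf)))
}

# Bond table (a1, a2, order) of an SDF instance.
sdf_bonds <- function(sdf) {
  bb <- ChemmineR::bondblock(sdf)
  data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
             order = as.integer(bb[, 3]))
}

# Cartesian coordinates (n x 3) of an SDF instance.
sdf_coords <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  xyz <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  storage.mode(xyz) <- "double"
  xyz
}

#' Molecular graph of a molecule
#'
#' Builds an igraph object with vertex attributes `element` and integer
#' `color` (element code) and an edge attribute `order` (bond order as in the
#' connection table; aromatic rings arrive Kekulized).
#'
#' @param x A SMILES string or a `ChemmineR::SDF` instance.
#' @return An `igraph` graph.
#' @export
mol_graph <- function(x) {
  if (is.character(x)) {
    txt <- smiles_to_sdf_string(x)
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    na <- as.integer(substr(lines[4], 1, 3))
    nb <- as.integer(substr(lines[4], 4, 6))
    if (is.na(nb) || nb == 0) {
      # bond-free molecules choke the SDF container; build the trivial graph
      el <- trimws(substr(lines[4 + seq_len(na)], 32, 34))
      g <- igraph::make_empty_graph(n = na, directed = FALSE)
      igraph::V(g)$element <- el
      igraph::V(g)$color <- element_code(el)
      igraph::E(g)$order <- integer(0)
      return(g)
    }
    sdfset <- methods::as(ChemmineR::read.SDFstr(lines), "SDFset")
    x <- sdfset[[1]]
  }
  stopifnot(methods::is(x, "SDF"))
  el <- sdf_elements(x)
  bonds <- sdf_bonds(x)
  g <- igraph::make_empty_graph(n = length(el), directed = FALSE)
  g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  igraph::V(g)$element <- el
  igraph::V(g)$color <- element_code(el)
  igraph::E(g)$order <- bonds$order
  g
}

# Stable small-integer codes for elements (VF2 needs integer colors).
element_code <- function(el) {
  codes <- c(H = 1L, C = 2L, N = 3L, O = 4L, S = 5L, P = 6L, F = 7L,
             Cl = 8L, Br = 9L, I = 10L, B = 11L, Si = 12L, "*" = 13L)
  out <- codes[el]
  out[is.na(out)] <- 14L + match(el[is.na(out)], unique(el[is.na(out)]))
  unname(out)
}

#' Match a molecular pattern graph in a target graph
#'
#' VF2 subgraph isomorphism on element colors, followed by bond-order
#' filtering: each pattern edge may declare an `orders` attribute (vector of
#' admissible bond orders); edges without it accept any order. All mappings,
#' including automorphic ones, are returned.
#'
#' @param target,pattern igraph objects from [mol_graph()] (pattern may carry
#'   an `orders` edge attribute).
#' @return List of integer vectors; element `i` of a vector is the target
#'   vertex matched to pattern vertex `i`.
#' @export
match_pattern <- function(target, pattern) {
  maps <- igraph::subgraph_isomorphisms(pattern, target, method = "vf2")
  if (length(maps) == 0) return(list())
  pe <- igraph::as_edgelist(pattern, names = FALSE)
  allowed <- if ("orders" %in% igraph::edge_attr_names(pattern)) {
    igraph::E(pattern)$orders
  } else {
    rep(list(NULL), nrow(pe))
  }
  keep <- vapply(maps, function(m) {
    m <- as.integer(m)
    for (k in seq_len(nrow(pe))) {
      if (is.null(allowed[[k]])) next
      eid <- igraph::get_edge_ids(target, c(m[pe[k, 1]], m[pe[k, 2]]))
      if (eid == 0) return(FALSE)
      if (!(igraph::E(target)$order[eid] %in% allowed[[k]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  lapply(maps[keep], as.integer)
}

#' Rooted SMILES of a single-molecule SDF text
#'
#' Writes the SMILES string beginning at a chosen atom (OpenBabel `-xf`),
#' which is what the reaction engine uses to obtain attachable fragments.
#'
#' @param sdf_text Molblock text (one molecule).
#' @param root 1-based atom index used as the first SMILES atom.
#' @return A SMILES string.
#' @keywords internal
rooted_smiles <- function(sdf_text, root) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sdf_text, tmp)
  out <- system2(ob_binary(), c(tmp, "-osmi", "-xn", paste0("-xf", root)),
                 stdout = TRUE, stderr = FALSE)
  out <- trimws(out[nzchar(trimws(out))])
  if (length(out) != 1) stop("rooted SMILES generation failed", call. = FALSE)
  out
}

# OpenBabel stores the 166 MACCS bits inside a zero-padded 256-bit block;
# only the first 166 columns are kept.
#' MACCS structural keys
#'
#' @param smiles Character vector of SMILES.
#' @return 0/1 integer matrix, one row per molecule, 166 MACCS bits.
#' @export
maccs_keys <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  src <- paste(smiles, collapse = "\n")
  rows <- ChemmineOB::forEachMol("SMI", src, function(m) {
    ChemmineOB::fingerprint_OB(list(m), "MACCS")
  })
  if (length(rows) != length(smiles)) {
    stop("fingerprinting dropped molecules (unparsable SMILES?)", call. = FALSE)
  }
  m <- do.call(rbind, lapply(rows, as.vector))
  m <- m[, seq_len(166), drop = FALSE]
  m <- (m != 0) * 1L
  storage.mode(m) <- "integer"
  rownames(m) <- names(smiles)
  m
}

#' Tanimoto similarity between fingerprint rows
#'
#' @param fps 0/1 matrix (rows = molecules).
#' @return Symmetric similarity matrix in `[0, 1]`; pairs of all-zero
#'   fingerprints get similarity 1 (identical empty key sets).
#' @export
tanimoto_matrix <- function(fps) {
  fps <- as.matrix(fps)
  storage.mode(fps) <- "double"
  common <- tcrossprod(fps)
  on_bits <- rowSums(fps)
  denom <- outer(on_bits, on_bits, "+") - common
  sim <- ifelse(denom > 0, common / denom, 1)
  diag(sim) <- 1
  sim
}
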