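# Building-block loading and role validation.
#
# Roles: thq_amine (a 1,2,3,4-tetrahydroisoquinoline bearing a secondary ring
# nitrogen, the only amine allowed to react), aldehyde (exactly one H-C=O),
# isocyanide (exactly one R-N+#C-, written charge-separated).

BLOCK_ROLES <- c("thq_amine", "aldehyde", "isocyanide")

# SMARTS used for role validation. Aldehyde: a carbonyl carbon carrying one H
# and a carbon substituent, or formaldehyde itself; formates/amides are
# excluded by the [#6] neighbour. Isocyanide: terminal charge-separated
# N+#C- with a substituted nitrogen.
ROLE_SMARTS <- list(
  aldehyde   = c("[#6X3H1](=[OX1])[#6]", "[CX3H2]=[OX1]"),
  isocyanide = c("[C-X1]#[N+X2]")
)

#' Pattern graph of the 1,2,3,4-tetrahydroisoquinoline core
#'
#' Vertices 1..10: N2, C3, C4, C4a, C5, C6, C7, C8, C8a, C1 (ring fusion at
#' C4a/C8a). Saturated-ring bonds require order 1; benzo-ring bonds accept
#' either Kekule order so any valid Kekulization of the aromatic ring matches.
#'
#' @return An igraph pattern suitable for [match_pattern()].
#' @keywords internal
thq_pattern <- function() {
  el <- c("N", rep("C", 9))
  edges <- rbind(
    c(1, 2), c(2, 3), c(3, 4),             # N2-C3-C4-C4a
    c(4, 5), c(5, 6), c(6, 7), c(7, 8), c(8, 9), c(9, 4),  # benzo
    c(9, 10), c(10, 1)                      # C8a-C1-N2
  )
  g <- igraph::make_empty_graph(n = 10, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$element <- el
  igraph::V(g)$color <- element_code(el)
  aromatic <- c(rep(FALSE, 3), rep(TRUE, 6), rep(FALSE, 2))
  igraph::E(g)$orders <- lapply(aromatic, function(a) if (a) c(1L, 2L) else 1L)
  g
}

#' Locate the reactive tetrahydroisoquinoline nitrogen
#'
#' Finds all embeddings of the THQ core and returns the index of the
#' secondary ring nitrogen. Exocyclic amines elsewhere on the block never
#' react. An additional Kekule sanity check requires every benzo carbon to
#' carry exactly one double bond inside the matched ring.
#'
#' @param graph Molecular graph from [mol_graph()].
#' @return Integer atom index, or `NA` with attribute `reason` when the core
#'   is absent, the nitrogen is not secondary, or several distinct candidate
#'   nitrogens exist.
#' @keywords internal
find_thq_nitrogen <- function(graph) {
  fail <- function(reason) structure(NA_integer_, reason = reason)
  maps <- match_pattern(graph, thq_pattern())
  maps <- Filter(function(m) thq_kekule_ok(graph, m), maps)
  if (length(maps) == 0) return(fail("no 1,2,3,4-tetrahydroisoquinoline core"))
  ns <- unique(vapply(maps, `[`, integer(1), 1L))
  deg <- igraph::degree(graph)
  ns <- ns[deg[ns] == 2]
  if (length(ns) == 0) return(fail("THQ ring nitrogen is not a secondary amine"))
  if (length(ns) > 1) return(fail("multiple THQ cores: reactive site ambiguous"))
  ns
}

# Each benzo carbon of a THQ match must have exactly one ring double bond.
thq_kekule_ok <- function(graph, map) {
  ring <- map[4:9]
  orders <- igraph::E(graph)$order
  dbl <- integer(6)
  pairs <- cbind(seq_len(6), c(2:6, 1))
  for (k in seq_len(6)) {
    eid <- igraph::get_edge_ids(graph, c(ring[pairs[k, 1]], ring[pairs[k, 2]]))
    if (orders[eid] == 2) {
      dbl[pairs[k, 1]] <- dbl[pairs[k, 1]] + 1L
      dbl[pairs[k, 2]] <- dbl[pairs[k, 2]] + 1L
    }
  }
  all(dbl == 1L)
}

#' Validate a building block against its role
#'
#' @param smiles SMILES string.
#' @param role One of `"thq_amine"`, `"aldehyde"`, `"isocyanide"`.
#' @return `TRUE`, or a character string naming the violated requirement.
#' @export
validate_block <- function(smiles, role) {
  role <- match.arg(role, BLOCK_ROLES)
  can <- canonical_smiles(smiles)
  if (is.na(can)) return("unparsable structure")
  if (grepl(".", can, fixed = TRUE)) return("structure is not a single fragment")
  if (role == "thq_amine") {
    n <- find_thq_nitrogen(mol_graph(can))
    if (is.na(n)) return(attr(n, "reason"))
    return(TRUE)
  }
  pats <- ROLE_SMARTS[[role]]
  counts <- vapply(pats, function(p) smarts_count(can, p), integer(1))
  total <- sum(counts)
  want <- if (role == "aldehyde") "exactly one H-C=O group" else
    "exactly one terminal isocyanide (written [N+]#[C-])"
  if (total != 1L) return(paste0(want, " required, found ", total))
  TRUE
}

#' Load a role-labelled building-block table
#'
#' Reads a CSV with columns `id`, `smiles`, `role` and validates every block
#' against its role's substructure requirements.
#'
#' @param path CSV file path, or a data frame with the same columns.
#' @return A `building_blocks` data frame with columns `id`, `smiles`
#'   (as given), `canonical` and `role`.
#' @export
#' @examples
#' df <- data.frame(id = "thq1", smiles = "C1Cc2ccccc2CN1", role = "thq_amine")
#' load_building_blocks(df)
load_building_blocks <- function(path) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "role")
  if (!all(need %in% names(df))) {
    stop("building-block table must have columns id, smiles, role", call. = FALSE)
  }
  df <- df[, need]
  if (anyDuplicated(df$id)) stop("duplicate building-block ids", call. = FALSE)
  bad_role <- !(df$role %in% BLOCK_ROLES)
  if (any(bad_role)) {
    stop("unknown role(s) at line(s) ", paste(which(bad_role), collapse = ", "),
         ": ", paste(unique(df$role[bad_role]), collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  df$canonical <- NA_character_
  for (i in seq_len(nrow(df))) {
    v <- validate_block(df$smiles[i], df$role[i])
    if (!isTRUE(v)) {
      problems <- c(problems, sprintf("line %d (%s, %s): %s",
                                      i, df$id[i], df$role[i], v))
    } else {
      df$canonical[i] <- canonical_smiles(df$smiles[i])
    }
  }
  if (length(problems)) {
    stop("invalid building blocks:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  df <- df[, c("id", "smiles", "canonical", "role")]
  class(df) <- c("building_blocks", "data.frame")
  df
}

#' @export
print.building_blocks <- function(x, ...) {
  tab <- table(factor(x$role, levels = BLOCK_ROLES))
  cat("Building-block set:", nrow(x), "blocks (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}
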