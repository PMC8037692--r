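# Ugi reaction engine.
#
# Both schemes couple a THQ secondary amine, an aldehyde and an isocyanide:
#   ugi_3cr:       R2NH + R'CHO + R''NC        -> R2N-CHR'-C(=O)-NH-R''
#   ugi_tetrazole: R2NH + R'CHO + R''NC + HN3  -> R2N-CHR'-C5(tetrazole)-N1R''
# (hydrazoic acid is an implicit reagent of the tetrazole route).
#
# Products are assembled by SMILES splicing: each block is reduced to a
# fragment string rooted at its attachment atom (OpenBabel rooted-SMILES
# output), and the scheme's skeleton glues the fragments together. The Ugi
# stereocentre is left unspecified; tetrazole regiochemistry is fixed to
# 1,5-disubstitution.

REACTION_SCHEMES <- c("ugi_3cr", "ugi_tetrazole")

# Skeleton SMARTS each product must satisfy (alpha-amino amide; aromatic
# 1,5-disubstituted tetrazole).
SCHEME_SMARTS <- c(
  ugi_3cr = "[#7X3]([#6])[CX4][CX3](=[OX1])[#7X3H1]",
  ugi_tetrazole = "[#6]n1c([#6])nnn1"
)

# Attachment-atom indices for each role, on the canonical-SMILES connection
# table. Returns list(root = atom index, drop = atoms consumed by the
# transform) or stops.
reactive_site <- function(graph, role) {
  el <- igraph::V(graph)$element
  deg <- igraph::degree(graph)
  orders <- igraph::E(graph)$order
  if (role == "thq_amine") {
    n <- find_thq_nitrogen(graph)
    if (is.na(n)) stop(attr(n, "reason"), call. = FALSE)
    return(list(root = n))
  }
  if (role == "aldehyde") {
    os <- which(el == "O" & deg == 1)
    for (o in os) {
      eid <- igraph::incident(graph, o)
      if (orders[eid] != 2) next
      c_at <- setdiff(igraph::ends(graph, eid, names = FALSE)[1, ], o)
      nb <- setdiff(as.integer(igraph::neighbors(graph, c_at)), o)
      if (length(nb) <= 1 && all(el[nb] == "C")) {
        return(list(root = o, carbonyl = c_at))
      }
    }
    stop("no H-C=O group found", call. = FALSE)
  }
  if (role == "isocyanide") {
    cs <- which(el == "C" & deg == 1)
    for (ci in cs) {
      eid <- igraph::incident(graph, ci)
      if (orders[eid] != 3) next
      n_at <- setdiff(igraph::ends(graph, eid, names = FALSE)[1, ], ci)
      if (el[n_at] == "N" && deg[n_at] == 2) return(list(root = ci))
    }
    stop("no terminal isocyanide group found", call. = FALSE)
  }
  stop("unknown role: ", role, call. = FALSE)
}

# Strip a fixed prefix from a rooted SMILES, failing loudly when the writer
# produced something unexpected.
strip_prefix <- function(smiles, prefix, what) {
  hit <- startsWith(smiles, prefix)
  if (!any(hit)) {
    stop("unexpected rooted SMILES for ", what, ": ", smiles, call. = FALSE)
  }
  substring(smiles, nchar(prefix[hit][1]) + 1L)
}

#' Attachable fragment of a building block
#'
#' Reduces a validated block to the SMILES fragment spliced into the product:
#' the whole amine rooted at its THQ ring nitrogen; the aldehyde side chain
#' R' (carbonyl consumed by the skeleton); the isocyanide written from its
#' nitrogen (`NR''`, amide branch) and from its side chain (`R''`, tetrazole
#' N1 substituent).
#'
#' @param smiles Block SMILES.
#' @param role Block role.
#' @return For `thq_amine`/`aldehyde` a single string; for `isocyanide` a
#'   character vector `c(amide = "N...", n1 = "...")`.
#' @keywords internal
block_fragment <- function(smiles, role) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("unparsable structure: ", smiles, call. = FALSE)
  sdf_text <- smiles_to_sdf_string(can)
  sdfset <- methods::as(
    ChemmineR::read.SDFstr(strsplit(sdf_text, "\n", fixed = TRUE)[[1]]),
    "SDFset")
  graph <- mol_graph(sdfset[[1]])
  site <- reactive_site(graph, role)
  rooted <- rooted_smiles(sdf_text, site$root)
  switch(role,
    thq_amine = {
      if (!startsWith(rooted, "N")) {
        stop("unexpected rooted SMILES for THQ amine: ", rooted, call. = FALSE)
      }
      rooted
    },
    aldehyde = strip_prefix(rooted, "O=C", "aldehyde"),
    isocyanide = {
      r <- strip_prefix(rooted, c("[C-]#[N+]", "[c-]#[n+]"), "isocyanide")
      c(amide = paste0("N", r), n1 = r)
    }
  )
}

# Splice fragments into a product SMILES for one scheme.
splice_product <- function(scheme, frag_amine, frag_ald, frag_iso) {
  mid <- if (nzchar(frag_ald)) paste0("(", frag_ald, ")") else ""
  if (scheme == "ugi_3cr") {
    paste0("C(", frag_amine, ")", mid, "C(=O)", frag_iso[["amide"]])
  } else {
    paste0("C(", frag_amine, ")", mid, "c1nnnn1", frag_iso[["n1"]])
  }
}

#' Apply an Ugi reaction scheme to one building-block triple
#'
#' @param scheme `"ugi_3cr"` or `"ugi_tetrazole"`.
#' @param amine,aldehyde,isocyanide SMILES strings of the three blocks
#'   (validated against their roles before reacting).
#' @return List with `smiles` (canonical product) and `scheme`.
#' @export
#' @examples
#' react("ugi_3cr", "C1Cc2ccccc2CN1", "C=O", "C[N+]#[C-]")
react <- function(scheme, amine, aldehyde, isocyanide) {
  scheme <- match.arg(scheme, REACTION_SCHEMES)
  for (b in list(c(amine, "thq_amine"), c(aldehyde, "aldehyde"),
                 c(isocyanide, "isocyanide"))) {
    v <- validate_block(b[1], b[2])
    if (!isTRUE(v)) stop(b[2], " block invalid: ", v, call. = FALSE)
  }
  prod <- splice_product(scheme,
                         block_fragment(amine, "thq_amine"),
                         block_fragment(aldehyde, "aldehyde"),
                         block_fragment(isocyanide, "isocyanide"))
  can <- canonical_smiles(prod)
  if (is.na(can)) stop("product assembly failed for scheme ", scheme, call. = FALSE)
  if (smarts_count(can, SCHEME_SMARTS[[scheme]]) < 1) {
    stop("product does not satisfy the ", scheme, " skeleton", call. = FALSE)
  }
  list(smiles = can, scheme = scheme)
}
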