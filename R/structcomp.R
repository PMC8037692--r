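# Receptor-crystal comparison: sequence identity, optimal superposition,
# per-residue deviation profiles. PDB parsing via bio3d; alignments via
# Biostrings.

#' Read a protein chain into a structure model
#'
#' @param path PDB file path.
#' @param chain Chain identifier (default `"A"`).
#' @param model Model number for multi-model files (default first).
#' @return A `structure_model`: list with `atoms` (data frame: `resno`,
#'   `resid`, `elety`, `element`, `x`, `y`, `z`), `sequence` (one-letter),
#'   `resnos` (ordered residue numbers), `chain`, `source`.
#' @export
read_structure <- function(path, chain = "A", model = 1) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  sel <- pdb$atom$chain == chain & pdb$atom$type == "ATOM"
  atoms <- pdb$atom[sel, c("resno", "resid", "elety", "elesy", "x", "y", "z")]
  if (nrow(atoms) == 0) stop("chain ", chain, " not found in ", path,
                             call. = FALSE)
  names(atoms)[4] <- "element"
  resnos <- unique(atoms$resno)
  seq1 <- vapply(resnos, function(r) {
    bio3d::aa321(atoms$resid[atoms$resno == r][1])
  }, character(1))
  structure(list(atoms = atoms, sequence = paste(seq1, collapse = ""),
                 resnos = resnos, chain = chain, source = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: chain", x$chain, "-", length(x$resnos), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, extension
#' 0.5 by default); identity = matched columns / aligned columns after
#' discarding terminal-gap columns (alternative denominators selectable).
#'
#' @param seq_a,seq_b Amino-acid strings (or `structure_model`s).
#' @param gap_opening,gap_extension Gap penalties.
#' @param denominator `"aligned"` (alignment length minus terminal gaps,
#'   default), `"shorter"` or `"longer"` sequence length.
#' @return Percent identity (0-100).
#' @export
pairwise_identity <- function(seq_a, seq_b, gap_opening = 10,
                              gap_extension = 0.5,
                              denominator = c("aligned", "shorter", "longer")) {
  denominator <- match.arg(denominator)
  seq_a <- as_sequence(seq_a); seq_b <- as_sequence(seq_b)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"
  if (!grepl(ok, seq_a) || !grepl(ok, seq_b)) {
    stop("non-amino-acid characters in sequence", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  non_term <- non_terminal_columns(a, b)
  matches <- sum(a == b & a != "-" & non_term)
  den <- switch(denominator,
                aligned = sum(non_term),
                shorter = min(nchar(seq_a), nchar(seq_b)),
                longer = max(nchar(seq_a), nchar(seq_b)))
  100 * matches / den
}

as_sequence <- function(x) {
  if (inherits(x, "structure_model")) return(x$sequence)
  as.character(x)
}

non_terminal_columns <- function(a, b) {
  n <- length(a)
  keep <- rep(TRUE, n)
  for (s in list(a, b)) {
    lead <- cumsum(s != "-") == 0
    trail <- rev(cumsum(rev(s) != "-") == 0)
    keep <- keep & !lead & !trail
  }
  keep
}

# Alignment-based residue pairing: returns data frame of paired residue
# numbers (pairing follows the sequence alignment, not residue numbering --
# orthologs may be offset).
pair_residues <- function(sm_a, sm_b, ...) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sm_a$sequence), Biostrings::AAString(sm_b$sequence),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  rows <- list()
  for (k in seq_along(a)) {
    if (a[k] != "-") ia <- ia + 1L
    if (b[k] != "-") ib <- ib + 1L
    if (a[k] != "-" && b[k] != "-") {
      rows[[length(rows) + 1L]] <- c(sm_a$resnos[ia], sm_b$resnos[ib])
    }
  }
  m <- do.call(rbind, rows)
  data.frame(resno_a = m[, 1], resno_b = m[, 2])
}

selection_atoms <- function(selection) {
  switch(selection,
         ca = "CA",
         backbone = c("N", "CA", "C", "O"),
         all = NULL)
}

# Paired coordinate matrices for a residue pairing under a selection.
paired_coords <- function(sm_a, sm_b, pairs, selection = "ca") {
  want <- selection_atoms(selection)
  xa <- list(); xb <- list(); res <- list()
  for (k in seq_len(nrow(pairs))) {
    aa <- sm_a$atoms[sm_a$atoms$resno == pairs$resno_a[k], ]
    bb <- sm_b$atoms[sm_b$atoms$resno == pairs$resno_b[k], ]
    names_common <- intersect(aa$elety, bb$elety)
    if (!is.null(want)) names_common <- intersect(names_common, want)
    names_common <- setdiff(names_common, grep("^H", names_common, value = TRUE))
    if (length(names_common) == 0) next
    xa[[length(xa) + 1L]] <-
      as.matrix(aa[match(names_common, aa$elety), c("x", "y", "z")])
    xb[[length(xb) + 1L]] <-
      as.matrix(bb[match(names_common, bb$elety), c("x", "y", "z")])
    res[[length(res) + 1L]] <- rep(pairs$resno_a[k], length(names_common))
  }
  list(a = do.call(rbind, xa), b = do.call(rbind, xb),
       resno = unlist(res))
}

#' Optimal superposition of two structures
#'
#' Pairs residues by sequence alignment, then computes the least-squares
#' rigid superposition (Kabsch) over the selected atoms.
#'
#' @param struct_a,struct_b `structure_model`s (`struct_b` is superposed
#'   onto `struct_a`).
#' @param selection `"ca"`, `"backbone"` or `"all"` (heavy atoms).
#' @return List: `rmsd` (after superposition), `transform`, `n_atoms`,
#'   `pairs`.
#' @export
superpose <- function(struct_a, struct_b,
                      selection = c("ca", "backbone", "all")) {
  selection <- match.arg(selection)
  pairs <- pair_residues(struct_a, struct_b)
  pc <- paired_coords(struct_a, struct_b, pairs, selection)
  if (is.null(pc$a) || nrow(pc$a) < 3) {
    stop("fewer than 3 paired atoms for superposition", call. = FALSE)
  }
  fit <- kabsch(pc$b, pc$a)
  list(rmsd = fit$rmsd, transform = fit$transform, n_atoms = nrow(pc$a),
       pairs = pairs)
}

#' Per-residue deviation profiles across a structural ensemble
#'
#' Superposes every structure onto the reference (global fit over the
#' selection), then reports the per-residue RMSD of the selection's atoms,
#' indexed by reference residue numbering. Unpairable residues leave gaps
#' (`NA`), not failures.
#'
#' @param structures List of `structure_model`s.
#' @param reference Reference `structure_model`.
#' @param selection `"ca"`, `"backbone"` or `"all"`.
#' @return A residues x structures matrix of per-residue RMSD (Angstrom),
#'   rownames = reference residue numbers.
#' @export
ensemble_rmsd_profile <- function(structures, reference,
                                  selection = c("ca", "backbone", "all")) {
  selection <- match.arg(selection)
  out <- matrix(NA_real_, nrow = length(reference$resnos),
                ncol = length(structures),
                dimnames = list(reference$resnos,
                                paste0("s", seq_along(structures))))
  for (j in seq_along(structures)) {
    sm <- structures[[j]]
    pairs <- pair_residues(reference, sm)
    pc <- paired_coords(reference, sm, pairs, selection)
    if (is.null(pc$a) || nrow(pc$a) < 3) next
    fit <- kabsch(pc$b, pc$a)
    fitted <- fit$transform(pc$b)
    dev2 <- rowSums((fitted - pc$a)^2)
    for (r in unique(pc$resno)) {
      out[as.character(r), j] <- sqrt(mean(dev2[pc$resno == r]))
    }
  }
  out
}

#' Fetch a PDB entry (network convenience)
#'
#' Downloads a PDB file from RCSB. Requires network access; every analysis
#' in this package also accepts local files, and the test suite never calls
#' this.
#'
#' @param id 4-character PDB id.
#' @param path Destination file (default tempfile).
#' @return The path to the downloaded file.
#' @export
fetch_pdb <- function(id, path = tempfile(fileext = ".pdb")) {
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  utils::download.file(url, path, quiet = TRUE)
  path
}
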