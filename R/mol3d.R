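# Lightweight 3D molecule container used by the conformer, pharmacophore and
# pose stages: element vector, coordinates, bond table, optional name/energy.

#' Construct a 3D molecule
#'
#' @param elements Character vector of element symbols.
#' @param xyz n x 3 numeric matrix (Angstrom).
#' @param bonds Data frame with columns `a1`, `a2`, `order` (1-based atom
#'   indices).
#' @param name Optional identifier.
#' @param energy Optional energy tag (kcal/mol).
#' @return An object of class `mol3d`.
#' @export
mol3d <- function(elements, xyz, bonds, name = "", energy = NA_real_) {
  xyz <- as.matrix(xyz)
  stopifnot(length(elements) == nrow(xyz), ncol(xyz) == 3,
            all(c("a1", "a2", "order") %in% names(bonds)))
  stopifnot(all(is.finite(xyz)))
  structure(list(elements = elements, xyz = xyz,
                 bonds = as.data.frame(bonds)[, c("a1", "a2", "order")],
                 name = name, energy = energy),
            class = "mol3d")
}

#' @export
print.mol3d <- function(x, ...) {
  heavy <- sum(x$elements != "H")
  cat("mol3d", if (nzchar(x$name)) paste0("'", x$name, "'"), ":",
      length(x$elements), "atoms (", heavy, "heavy ),",
      nrow(x$bonds), "bonds")
  if (!is.na(x$energy)) cat(", energy", format(x$energy), "kcal/mol")
  cat("\n")
  invisible(x)
}

# igraph view of a mol3d (same attributes as mol_graph()).
mol3d_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = length(mol$elements), directed = FALSE)
  g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  igraph::V(g)$element <- mol$elements
  igraph::V(g)$color <- element_code(mol$elements)
  igraph::E(g)$order <- mol$bonds$order
  g
}

# Heavy-atom index vector.
heavy_atoms <- function(mol) which(mol$elements != "H")

#' Read molecules from an SDF file
#'
#' @param file Path to an SDF/MOL file.
#' @return List of [mol3d()] objects; molecule-level `<energy>`/`Energy` data
#'   fields are parsed into the `energy` slot when present.
#' @export
read_sdf_mols <- function(file) {
  sdfset <- ChemmineR::read.SDFset(file, skipErrors = TRUE)
  lapply(seq_along(sdfset), function(i) {
    sdf <- sdfset[[i]]
    dat <- ChemmineR::datablock(sdf)
    en <- NA_real_
    hit <- grep("^energy$", names(dat), ignore.case = TRUE)
    if (length(hit)) en <- suppressWarnings(as.numeric(dat[[hit[1]]]))
    mol3d(sdf_elements(sdf), sdf_coords(sdf), sdf_bonds(sdf),
          name = ChemmineR::sdfid(sdf), energy = en)
  })
}

#' Write molecules to an SDF file
#'
#' Serializes `mol3d` objects as V2000 molblocks; a non-`NA` energy slot is
#' written as an `<energy>` data field.
#'
#' @param mols A `mol3d` or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sdf_mols <- function(mols, file) {
  if (inherits(mols, "mol3d")) mols <- list(mols)
  con <- file(file, "w")
  on.exit(close(con))
  for (mol in mols) {
    na <- length(mol$elements); nb <- nrow(mol$bonds)
    lines <- c(
      mol$name, " mcrpharm", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              mol$xyz[, 1], mol$xyz[, 2], mol$xyz[, 3], mol$elements),
      if (nb > 0) sprintf("%3d%3d%3d  0  0  0  0",
                          mol$bonds$a1, mol$bonds$a2, mol$bonds$order),
      "M  END")
    if (!is.na(mol$energy)) {
      lines <- c(lines, "> <energy>", format(mol$energy), "")
    }
    writeLines(c(lines, "$$$$"), con)
  }
  invisible(file)
}

# Rigid-transform a mol3d's coordinates.
transform_mol <- function(mol, fn) {
  mol$xyz <- fn(mol$xyz)
  mol
}
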