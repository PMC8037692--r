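# Exhaustive combinatorial enumeration (the CCC stage).

#' Enumerate an Ugi combinatorial library
#'
#' Forms the full Cartesian product (THQ amine x aldehyde x isocyanide) under
#' one reaction scheme. Fragments are precomputed once per block, products are
#' assembled by SMILES splicing, canonicalized in one batch and deduplicated
#' by canonical form (stereochemistry-free).
#'
#' @param blocks A `building_blocks` table from [load_building_blocks()] (or a
#'   data frame with columns `id`, `smiles`, `role`, validated on entry).
#' @param scheme `"ugi_3cr"` or `"ugi_tetrazole"`.
#' @param validate_sample Number of products per library to re-check against
#'   the scheme's skeleton SMARTS (a spot check; 0 disables).
#' @return A `compound_library` data frame with columns `canonical_key`
#'   (canonical product SMILES, unique within the library), `thq_id`,
#'   `aldehyde_id`, `isocyanide_id`, `scheme`. Product structures are
#'   regenerable from the provenance triple with [react()].
#' @export
enumerate_library <- function(blocks, scheme = c("ugi_3cr", "ugi_tetrazole"),
                              validate_sample = 25) {
  scheme <- match.arg(scheme)
  if (!inherits(blocks, "building_blocks")) blocks <- load_building_blocks(blocks)
  parts <- split(blocks, factor(blocks$role, levels = BLOCK_ROLES))
  sizes <- vapply(parts, nrow, integer(1))
  if (any(sizes == 0)) {
    stop("empty role class: ", paste(names(sizes)[sizes == 0], collapse = ", "),
         call. = FALSE)
  }
  amines <- parts$thq_amine; alds <- parts$aldehyde; isos <- parts$isocyanide

  frag_a <- vapply(amines$canonical, block_fragment, character(1),
                   role = "thq_amine", USE.NAMES = FALSE)
  frag_p <- vapply(alds$canonical, block_fragment, character(1),
                   role = "aldehyde", USE.NAMES = FALSE)
  frag_i <- lapply(isos$canonical, block_fragment, role = "isocyanide")
  iso_part <- vapply(frag_i, function(f) {
    if (scheme == "ugi_3cr") f[["amide"]] else f[["n1"]]
  }, character(1))

  grid <- expand.grid(a = seq_len(nrow(amines)), p = seq_len(nrow(alds)),
                      i = seq_len(nrow(isos)), KEEP.OUT.ATTRS = FALSE)
  mid <- ifelse(nzchar(frag_p), paste0("(", frag_p, ")"), "")
  skeleton <- if (scheme == "ugi_3cr") "C(=O)" else "c1nnnn1"
  raw <- paste0("C(", frag_a[grid$a], ")", mid[grid$p], skeleton, iso_part[grid$i])

  keys <- canonical_smiles_chunked(raw)
  if (anyNA(keys)) {
    stop(sum(is.na(keys)), " products failed canonicalization", call. = FALSE)
  }

  lib <- data.frame(canonical_key = keys,
                    thq_id = amines$id[grid$a],
                    aldehyde_id = alds$id[grid$p],
                    isocyanide_id = isos$id[grid$i],
                    scheme = scheme, stringsAsFactors = FALSE)
  lib <- lib[!duplicated(lib$canonical_key), , drop = FALSE]
  rownames(lib) <- NULL

  if (validate_sample > 0 && nrow(lib) > 0) {
    idx <- unique(round(seq(1, nrow(lib), length.out = min(validate_sample, nrow(lib)))))
    bad <- smarts_count(lib$canonical_key[idx], SCHEME_SMARTS[[scheme]]) < 1
    if (any(bad)) {
      stop("enumerated product(s) violate the ", scheme, " skeleton invariant",
           call. = FALSE)
    }
  }

  structure(lib,
            class = c("compound_library", "data.frame"),
            scheme = scheme,
            role_counts = sizes,
            n_combinations = nrow(grid))
}

# Canonicalize in chunks to keep single OpenBabel calls modest.
canonical_smiles_chunked <- function(smiles, chunk = 20000L) {
  if (length(smiles) <= chunk) return(canonical_smiles(smiles))
  out <- character(length(smiles))
  starts <- seq(1L, length(smiles), by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, length(smiles))
    out[s:e] <- canonical_smiles(smiles[s:e])
  }
  out
}

#' @export
print.compound_library <- function(x, ...) {
  rc <- attr(x, "role_counts")
  cat("Compound library (", attr(x, "scheme"), "): ", nrow(x),
      " unique products from ", attr(x, "n_combinations"),
      " combinations (", paste(rc, collapse = " x "), " blocks)\n", sep = "")
  invisible(x)
}

#' @export
summary.compound_library <- function(object, ...) {
  cat("Scheme:           ", attr(object, "scheme"), "\n")
  cat("Blocks per role:  ",
      paste(names(attr(object, "role_counts")),
            attr(object, "role_counts"), sep = "=", collapse = ", "), "\n")
  cat("Combinations:     ", attr(object, "n_combinations"), "\n")
  cat("Unique products:  ", nrow(object), "\n")
  invisible(object)
}

#' Regenerate a product structure from its provenance triple
#'
#' @param library A `compound_library`.
#' @param blocks The building-block table used for enumeration.
#' @param record Row index into `library`.
#' @return Canonical product SMILES (equal to the stored `canonical_key`).
#' @export
regenerate_product <- function(library, blocks, record) {
  row <- library[record, ]
  smi <- function(id) blocks$smiles[match(id, blocks$id)]
  react(row$scheme, smi(row$thq_id), smi(row$aldehyde_id),
        smi(row$isocyanide_id))$smiles
}

#' Overlap between two enumerated libraries
#'
#' Reports per-library unique counts and the number of canonical structures
#' shared between the two (structures reachable by both reaction schemes).
#'
#' @param lib1,lib2 `compound_library` objects.
#' @return List with `n1`, `n2`, `shared`, `total_unique`.
#' @export
library_overlap <- function(lib1, lib2) {
  shared <- length(intersect(lib1$canonical_key, lib2$canonical_key))
  list(n1 = nrow(lib1), n2 = nrow(lib2), shared = shared,
       total_unique = nrow(lib1) + nrow(lib2) - shared)
}
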