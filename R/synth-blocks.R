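# Synthetic building-block generator.
#
# Emulates the study's block inventory shape: 32 substituted
# 1,2,3,4-tetrahydroisoquinolines, 4 aldehydes and 657 isocyanides by
# default. Structures are constructed from fixed substituent vocabularies so
# the generated table is deterministic (byte-identical across calls), every
# block passes its role validation, and all blocks are pairwise structurally
# distinct under canonicalization.

# Aromatic-ring substituents placed on the THQ benzo ring: methyl, hydroxyl,
# amino (deliberately: an unreactive exocyclic amine), fluoro, chloro, bromo,
# methoxy, hydroxymethyl.
THQ_SUBSTITUENTS <- c("C", "O", "N", "F", "Cl", "Br", "OC", "CO")

# Aldehyde vocabulary: formaldehyde, acetaldehyde, glycolaldehyde,
# benzaldehyde.
ALDEHYDE_VOCAB <- c("C=O", "CC=O", "OCC=O", "O=Cc1ccccc1")

# Isocyanide side-chain pool pieces.
ISO_ARYL_SUBS <- c("C", "N", "O", "F", "Cl", "Br", "OC", "C(F)(F)F",
                   "CC", "OCC", "C#N", "CO")
ISO_LINKERS <- c("", "C", "CC", "CCC")

#' Generate a synthetic building-block table
#'
#' @param n_thq,n_ald,n_iso Number of blocks per role (defaults 32/4/657,
#'   the study-condition inventory sizes).
#' @param seed Unused for content (generation is deterministic) but kept in
#'   the signature for interface uniformity with the other generators.
#' @return A data frame with columns `id`, `smiles`, `role`, loadable with
#'   [load_building_blocks()].
#' @export
#' @examples
#' head(gen_building_blocks(n_thq = 2, n_ald = 2, n_iso = 3))
gen_building_blocks <- function(n_thq = 32, n_ald = 4, n_iso = 657,
                                seed = NULL) {
  stopifnot(n_thq > 0, n_ald > 0, n_iso > 0)
  thq <- character(0)
  for (x in THQ_SUBSTITUENTS) {
    thq <- c(thq,
             sprintf("C1Cc2c(%s)cccc2CN1", x),
             sprintf("C1Cc2cc(%s)ccc2CN1", x),
             sprintf("C1Cc2ccc(%s)cc2CN1", x),
             sprintf("C1Cc2cccc(%s)c2CN1", x))
  }
  thq <- pick_distinct(thq, n_thq, "thq_amine")

  ald <- pick_distinct(ALDEHYDE_VOCAB, n_ald, "aldehyde")

  pool <- character(0)
  # alkyl / alicyclic side chains
  pool <- c(pool, "C", "CC", "CCC", "CCCC", "CCCCC", "C(C)C", "CC(C)C",
            "CC(C)(C)C", "C1CCCCC1", "C1CCCC1", "CC1CCCCC1", "C1CC1",
            "CC(C)CC", "CCC(C)C", "CCOC", "CCO")
  # mono-substituted aryl (three positions) with optional alkyl linker
  aryl <- "c1ccccc1"
  for (x in ISO_ARYL_SUBS) {
    aryl <- c(aryl, sprintf("c1ccc(%s)cc1", x), sprintf("c1cccc(%s)c1", x),
              sprintf("c1(%s)ccccc1", x))
  }
  # 3,4-disubstituted aryl
  two <- expand.grid(a = ISO_ARYL_SUBS, b = ISO_ARYL_SUBS,
                     stringsAsFactors = FALSE)
  aryl2 <- sprintf("c1cc(%s)c(%s)cc1", two$a, two$b)
  # heteroaryl cores (indolyl as in the tetrazole exemplar, pyridyl, furyl,
  # thienyl)
  het <- c("c1ccc2[nH]ccc2c1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
           "c1cnc2ccccc2c1")
  for (lk in ISO_LINKERS) {
    pool <- c(pool, paste0(c(aryl, aryl2, het), lk))
  }
  iso <- pick_distinct(paste0(pool, "[N+]#[C-]"), n_iso, "isocyanide")

  data.frame(
    id = c(sprintf("thq%03d", seq_len(n_thq)),
           sprintf("ald%03d", seq_len(n_ald)),
           sprintf("iso%03d", seq_len(n_iso))),
    smiles = c(thq, ald, iso),
    role = rep(c("thq_amine", "aldehyde", "isocyanide"),
               c(n_thq, n_ald, n_iso)),
    stringsAsFactors = FALSE
  )
}

# First n structurally distinct members of a candidate pool, in pool order.
pick_distinct <- function(pool, n, role) {
  can <- canonical_smiles(pool)
  ok <- !is.na(can) & !duplicated(can)
  pool <- pool[ok]
  if (length(pool) < n) {
    stop("substituent vocabulary too small for ", n, " distinct ", role,
         " blocks (", length(pool), " available)", call. = FALSE)
  }
  pool[seq_len(n)]
}
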