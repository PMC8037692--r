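# MM/PBSA-style aggregation over per-frame energy component tables.
#
# The solvers are upstream: this module defines the tabular interchange
# format (per-frame molecular-mechanics, polar- and nonpolar-solvation
# differences, complex - receptor - ligand) and all downstream arithmetic.
# The entropy term is omitted from the decomposition on purpose (the
# single-trajectory approximation reported here aggregates the three stated
# components).

ENERGY_COMPONENTS <- c("dE_MM", "dG_polar", "dG_nonpolar")

#' Read a per-frame energy table
#'
#' CSV schema: `frame`, `dE_MM`, `dG_polar`, `dG_nonpolar` (kcal/mol), plus
#' optional per-residue columns named `res_<resno>` carrying per-residue
#' contributions.
#'
#' @param path CSV file.
#' @return An `energy_frames` data frame.
#' @export
read_energy_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("frame", ENERGY_COMPONENTS)
  if (!all(need %in% names(df))) {
    stop("energy table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("energy_frames", "data.frame")
  df
}

#' Per-frame binding energy
#'
#' `dG = dE_MM + dG_polar + dG_nonpolar` for each frame.
#'
#' @param frames An `energy_frames` data frame (or one row).
#' @return Numeric vector of per-frame binding energies (kcal/mol).
#' @export
frame_binding_energy <- function(frames) {
  miss <- setdiff(ENERGY_COMPONENTS, names(frames))
  if (length(miss)) {
    stop("missing component(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  vals <- frames[, ENERGY_COMPONENTS, drop = FALSE]
  if (anyNA(vals)) stop("missing component values", call. = FALSE)
  rowSums(vals)
}

#' Summarize a binding-energy trajectory
#'
#' Means and standard deviations per component and for the total, plus a
#' fluctuation flag when the total's SD exceeds a threshold (the
#' large-energy-fluctuation warning).
#'
#' @param frames An `energy_frames` data frame (>= 2 frames).
#' @param fluctuation_threshold SD (kcal/mol) above which the flag raises.
#' @return An `energy_summary`: list with `mean`, `sd` (named vectors over
#'   components + `total`), `series` (per-frame totals), `fluctuation_flag`.
#' @export
summarize_energy <- function(frames, fluctuation_threshold = 10) {
  stopifnot(nrow(frames) >= 2)
  total <- frame_binding_energy(frames)
  comp <- frames[, ENERGY_COMPONENTS, drop = FALSE]
  means <- c(colMeans(comp), total = mean(total))
  sds <- c(vapply(comp, sd, numeric(1)), total = sd(total))
  structure(list(mean = means, sd = sds, series = total,
                 fluctuation_flag = unname(sds["total"] > fluctuation_threshold),
                 fluctuation_threshold = fluctuation_threshold),
            class = "energy_summary")
}

#' @export
print.energy_summary <- function(x, ...) {
  cat("Binding energy over", length(x$series), "frames (kcal/mol):\n")
  for (k in names(x$mean)) {
    cat(sprintf("  %-12s %8.3f +/- %.3f\n", k, x$mean[[k]], x$sd[[k]]))
  }
  if (x$fluctuation_flag) {
    cat("  [flag] large energy fluctuations (SD >",
        x$fluctuation_threshold, "kcal/mol)\n")
  }
  invisible(x)
}

#' Per-residue energy decomposition map
#'
#' Time-mean contribution of each residue; residues with negative mean
#' contributions are classified favorable, positive unfavorable, zero
#' neutral.
#'
#' @param frames An `energy_frames` data frame with `res_<n>` columns (the
#'   same residue set in every row).
#' @return Data frame: `resno`, `mean`, `sd`, `class` (favorable /
#'   unfavorable / neutral).
#' @export
per_residue_map <- function(frames) {
  res_cols <- grep("^res_", names(frames), value = TRUE)
  if (length(res_cols) == 0) {
    stop("no per-residue columns (res_<n>) present", call. = FALSE)
  }
  vals <- frames[, res_cols, drop = FALSE]
  if (anyNA(vals)) {
    stop("inconsistent per-residue terms across frames", call. = FALSE)
  }
  m <- colMeans(vals)
  s <- vapply(vals, sd, numeric(1))
  cls <- ifelse(m < 0, "favorable", ifelse(m > 0, "unfavorable", "neutral"))
  data.frame(resno = as.integer(sub("^res_", "", res_cols)),
             mean = unname(m), sd = unname(s), class = unname(cls))
}
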