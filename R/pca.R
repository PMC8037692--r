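# Non-redundant PCA over the descriptor table.

#' Correlation-pruned principal component analysis
#'
#' Prunes correlated descriptors down to a compact non-redundant set, then
#' runs PCA on the standardized survivors. Pruning is greedy: while more than
#' `keep` descriptors remain and some pair exceeds the correlation threshold,
#' the lower-variance member of the most correlated pair is removed (variance
#' measured on standardized scale uses the raw variance ranking). If no pair
#' exceeds the threshold but more than `keep` descriptors remain, the `keep`
#' highest-variance descriptors are retained. Constant columns are dropped
#' with a warning. Pruning is idempotent: applied to its own output it
#' changes nothing.
#'
#' @param table A `descriptor_table` or numeric data frame.
#' @param correlation_threshold Absolute Pearson correlation above which a
#'   pair is redundant (default 0.9).
#' @param keep Number of descriptors to retain (default 10).
#' @return List with `scores`, `loadings`, `sdev`, `variance_explained`,
#'   `kept` (descriptor names), `dropped_constant`.
#' @export
pca_nonredundant <- function(table, correlation_threshold = 0.9, keep = 10) {
  num <- table[, vapply(table, is.numeric, logical(1)), drop = FALSE]
  num <- num[, setdiff(names(num), c("flag")), drop = FALSE]
  all_na <- vapply(num, function(v) all(is.na(v)), logical(1))
  num <- num[, !all_na, drop = FALSE]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  if (nrow(num) < 3) stop("too few complete rows for PCA", call. = FALSE)
  vars <- vapply(num, stats::var, numeric(1))
  const <- names(vars)[vars < .Machine$double.eps]
  if (length(const)) {
    warning("dropping constant descriptor(s): ", paste(const, collapse = ", "),
            call. = FALSE)
    num <- num[, setdiff(names(num), const), drop = FALSE]
    vars <- vars[setdiff(names(vars), const)]
  }
  kept <- prune_correlated(num, correlation_threshold, keep)
  if (length(kept) < 2) stop("fewer than 2 descriptors survive pruning",
                             call. = FALSE)
  X <- scale(as.matrix(num[, kept, drop = FALSE]))
  fit <- prcomp(X, center = FALSE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, loadings = fit$rotation, sdev = fit$sdev,
       variance_explained = ve, kept = kept, dropped_constant = const)
}

#' Greedy correlation pruning of descriptor columns
#'
#' @param num Numeric data frame.
#' @param threshold Absolute correlation threshold.
#' @param keep Target descriptor count.
#' @return Character vector of retained column names.
#' @export
prune_correlated <- function(num, threshold = 0.9, keep = 10) {
  cols <- names(num)
  vars <- vapply(num, stats::var, numeric(1))
  repeat {
    if (length(cols) <= keep) break
    cm <- abs(cor(num[, cols, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm, na.rm = TRUE) <= threshold) break
    worst <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- cols[worst]
    drop <- pair[which.min(vars[pair])]
    cols <- setdiff(cols, drop)
  }
  if (length(cols) > keep) {
    cols <- cols[order(vars[cols], decreasing = TRUE)][seq_len(keep)]
    cols <- names(num)[names(num) %in% cols]   # stable original order
  }
  cols
}
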