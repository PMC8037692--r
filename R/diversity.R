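# Chemical-diversity analysis: seeded library sampling, MACCS/Tanimoto
# dissimilarity, t-SNE embedding, silhouette-guided k-means.

#' Randomly sample a compound library
#'
#' @param library A `compound_library` (or data frame with `canonical_key`).
#' @param n Sample size (default 1500, the diversity-panel size).
#' @param seed Integer seed; the same seed reproduces the same subset.
#' @return The sampled rows, in stable (library) order.
#' @export
sample_library <- function(library, n = 1500, seed = 1) {
  if (n > nrow(library)) {
    stop("sample size ", n, " exceeds library size ", nrow(library),
         call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(nrow(library), n))
  out <- library[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' MACCS/Tanimoto diversity embedding
#'
#' Computes the 166-bit MACCS keys, converts pairwise Tanimoto similarity to
#' the dissimilarity `1 - T`, and embeds with exact t-SNE. The embedding is
#' stochastic but seed-reproducible and intended as a qualitative map; all
#' quantitative downstream work (clustering) runs on the embedding
#' coordinates, and the dissimilarity matrix itself is returned for exact
#' analyses.
#'
#' @param smiles Character vector (>= 3 x perplexity molecules).
#' @param perplexity t-SNE perplexity (default 50).
#' @param components Embedding dimensionality (default 2).
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations.
#' @return An `embedding_result`: list with `coords` (n x components),
#'   `dissimilarity` (n x n), `perplexity`, `seed`.
#' @export
diversity_embedding <- function(smiles, perplexity = 50, components = 2,
                                seed = 1, max_iter = 400) {
  n <- length(smiles)
  if (n < 3 * perplexity) {
    stop("need at least 3 x perplexity = ", 3 * perplexity,
         " molecules, got ", n, call. = FALSE)
  }
  fps <- maccs_keys(smiles)
  sim <- tanimoto_matrix(fps)
  D <- 1 - sim
  if (all(D < 1e-12)) {
    stop("degenerate input: all fingerprints identical", call. = FALSE)
  }
  coords <- tsne_exact(D, perplexity = perplexity, components = components,
                       seed = seed, max_iter = max_iter)
  structure(list(coords = coords, dissimilarity = D,
                 perplexity = perplexity, seed = seed),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("embedding_result:", nrow(x$coords), "molecules,",
      ncol(x$coords), "components, perplexity", x$perplexity, "\n")
  invisible(x)
}

#' Exact t-SNE on a dissimilarity matrix
#'
#' Plain (non-tree-accelerated) t-SNE: per-point bandwidths calibrated to
#' the target perplexity by bisection, early exaggeration, momentum gradient
#' descent. Quadratic cost per iteration; intended for panels of a few
#' thousand points.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param perplexity Target perplexity (< (n-1)/3).
#' @param components Output dimensionality.
#' @param seed Seed for the Gaussian initialization.
#' @param max_iter Iterations.
#' @param eta Learning rate.
#' @return n x components coordinate matrix.
#' @export
tsne_exact <- function(D, perplexity = 30, components = 2, seed = 1,
                       max_iter = 400, eta = 200) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(isSymmetric(unname(D)), n >= 4)
  P <- matrix(0, n, n)
  D2 <- D^2
  for (i in seq_len(n)) {
    P[i, ] <- calibrate_row(D2[i, ], i, perplexity)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.xmin] <- .Machine$double.xmin
  Y <- with_seed(seed, matrix(rnorm(n * components, sd = 1e-4), n, components))
  G <- matrix(0, n, n)
  inc <- matrix(0, n, components)
  for (iter in seq_len(max_iter)) {
    mult <- if (iter <= 100) 12 else 1
    momentum <- if (iter <= 250) 0.5 else 0.8
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.xmin] <- .Machine$double.xmin
    W <- (mult * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    inc <- momentum * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# Row-conditional probabilities at a bisected bandwidth hitting the target
# perplexity.
calibrate_row <- function(d2row, i, perplexity, tol = 1e-5, max_tries = 60) {
  d2 <- d2row[-i]
  beta <- 1; beta_min <- -Inf; beta_max <- Inf
  target <- log(perplexity)
  for (k in seq_len(max_tries)) {
    w <- exp(-d2 * beta)
    s <- sum(w)
    if (s <= 0) { H <- 0; p <- rep(0, length(d2)) }
    else {
      p <- w / s
      H <- -sum(p[p > 0] * log(p[p > 0]))
    }
    diff <- H - target
    if (abs(diff) < tol) break
    if (diff > 0) { beta_min <- beta; beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2 }
    else { beta_max <- beta; beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2 }
  }
  out <- numeric(length(d2row))
  out[-i] <- p
  out
}

#' Silhouette-guided k-means clustering
#'
#' Runs seeded k-means over a range of cluster counts and keeps the k with
#' the highest mean silhouette width.
#'
#' @param coords Numeric matrix (e.g. embedding coordinates) or an
#'   `embedding_result`.
#' @param k_range Candidate cluster counts (all in `[2, n - 1]`).
#' @param seed Seed for centroid initialization.
#' @param nstart k-means restarts per k.
#' @return List with `labels` (1-based cluster ids), `k`, `silhouette`
#'   (named vector of mean widths per candidate k), and `low_structure`
#'   (TRUE when even the best silhouette is weak, < 0.4 -- the level a
#'   single unstructured blob typically stays under).
#' @export
cluster_by_silhouette <- function(coords, k_range = 2:8, seed = 1,
                                  nstart = 10) {
  if (inherits(coords, "embedding_result")) coords <- coords$coords
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within [2, n-1]", call. = FALSE)
  }
  d <- dist(coords)
  sil <- setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (j in seq_along(k_range)) {
    fit <- with_seed(seed + k_range[j],
                     kmeans(coords, centers = k_range[j], nstart = nstart))
    fits[[j]] <- fit
    sil[j] <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
  }
  best <- which.max(sil)
  low <- sil[best] < 0.4
  if (low) {
    warning("weak cluster structure: best mean silhouette ",
            round(sil[best], 3), call. = FALSE)
  }
  list(labels = fits[[best]]$cluster, k = k_range[best], silhouette = sil,
       low_structure = low)
}
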