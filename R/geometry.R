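# Rigid-body geometry: Kabsch superposition, RMSD variants, axis rotations,
# minimum-image distances.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `ref`.
#'
#' @param mobile,ref n x 3 coordinate matrices with paired rows (n >= 3).
#' @return List with `R` (3 x 3 rotation), `t` (translation), `rmsd`, and
#'   `transform(X)` applying the fit to arbitrary coordinates.
#' @export
kabsch <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref), nrow(mobile) >= 3)
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)               # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  transform <- function(X) sweep(sweep(X, 2, cm) %*% t(R), 2, cr, "+")
  list(R = R, t = cr - as.vector(R %*% cm), rmsd = rmsd, transform = transform)
}

#' Root-mean-square deviation between paired coordinates
#'
#' @param a,b n x 3 matrices with paired rows.
#' @param superpose If `TRUE`, optimally superpose first (Kabsch); otherwise
#'   the in-place deviation is returned (both structures assumed to share a
#'   frame, the crystallographic convention).
#' @return RMSD in the input units.
#' @export
rmsd_coords <- function(a, b, superpose = FALSE) {
  stopifnot(nrow(a) == nrow(b))
  if (superpose) return(kabsch(a, b)$rmsd)
  sqrt(mean(rowSums((a - b)^2)))
}

# Rotate points by `angle` (radians) about the axis through p1 -> p2
# (Rodrigues formula).
rotate_about_axis <- function(coords, p1, p2, angle) {
  k <- p2 - p1
  k <- k / sqrt(sum(k^2))
  X <- sweep(coords, 2, p1)
  cosA <- cos(angle); sinA <- sin(angle)
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) * cosA + sinA * kx + (1 - cosA) * tcrossprod(k)
  sweep(X %*% t(R), 2, p1, "+")
}

#' Minimum-image distances under an orthorhombic periodic box
#'
#' @param points n x 3 matrix.
#' @param center Length-3 vector.
#' @param box Length-3 box edge lengths, or `NULL` for no periodicity.
#' @return Numeric vector of distances.
#' @export
min_image_dist <- function(points, center, box = NULL) {
  d <- sweep(points, 2, center)
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  sqrt(rowSums(d^2))
}

# All permutations of 1..n (n small; guarded).
permutations <- function(n) {
  if (n > 8) stop("permutation enumeration limited to 8 elements", call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Minimum-cost one-to-one assignment of rows to columns of a squared-cost
# matrix, by exhaustive permutation (feature counts here are small). Returns
# list(cols, cost = sum of selected entries).
best_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) >= n)
  perms <- permutations(ncol(cost))
  best <- NULL; best_cost <- Inf
  for (r in seq_len(nrow(perms))) {
    sel <- perms[r, seq_len(n)]
    cc <- sum(cost[cbind(seq_len(n), sel)])
    if (cc < best_cost) { best_cost <- cc; best <- sel }
  }
  list(cols = best, cost = best_cost)
}
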