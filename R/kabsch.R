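#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' between two coordinate sets, via the SVD of the weighted cross-covariance
#' matrix with the usual determinant correction so reflections are never
#' returned.
#'
#' @param mobile,reference `n x 3` coordinate matrices (Angstrom), `n >= 3`,
#'   same atom order.
#' @param weights Optional non-negative per-atom weights (e.g. masses);
#'   default equal weights.
#' @return A list with `rotation` (3x3, determinant +1), `translation`
#'   (length 3), `rmsd` (Angstrom) and `fitted` (the transformed mobile
#'   coordinates). The transform maps mobile point `p` to
#'   `rotation %*% p + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be n x 3 matrices of equal size.",
         call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3L) stop("Superposition needs at least 3 atoms.", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)

  sq <- svd(Q * sqrt(w))
  if (sq$d[2] < 1e-8 * max(sq$d[1], 1e-300)) {
    stop("Degenerate (collinear) reference geometry: rotation is not determined.",
         call. = FALSE)
  }

  H <- t(P * w) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)

  fitted <- P %*% t(R)
  msd <- sum(w * rowSums((fitted - Q)^2))
  fitted <- sweep(fitted, 2, cr, `+`)
  list(
    rotation = R,
    translation = as.numeric(cr - R %*% cm),
    rmsd = sqrt(max(msd, 0)),
    fitted = fitted
  )
}

# RMSD without superposition, equal or supplied weights
.raw_rmsd <- function(a, b, weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(a)) else weights
  w <- w / sum(w)
  sqrt(sum(w * rowSums((a - b)^2)))
}
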