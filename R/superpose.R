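#' Optimal rigid superposition (Kabsch/SVD)
#'
#' Finds the proper rotation \code{R} and translation \code{v} minimizing the
#' index-paired RMSD between \code{R \%*\% model[i,] + v} and
#' \code{target[i,]}.  Reflections are excluded: the sign of the smallest
#' singular value is corrected so \code{det(R) = +1}.
#'
#' @param model n x 3 coordinate matrix (n >= 3, not all collinear).
#' @param target n x 3 coordinate matrix paired row-by-row with \code{model}.
#' @return List with \code{rotation} (3x3), \code{translation} (3-vector) and
#'   \code{rmsd} (Angstrom).
#' @examples
#' m <- matrix(rnorm(12), 4, 3)
#' fit <- kabsch_superpose(m, m)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(model, target) {
  model <- rbind(model); target <- rbind(target)
  stopifnot(ncol(model) == 3L, ncol(target) == 3L)
  n <- nrow(model)
  if (n < 3L || nrow(target) != n)
    stop("need matched point sets with at least 3 points")
  cm <- colMeans(model); ct <- colMeans(target)
  a <- sweep(model, 2L, cm); b <- sweep(target, 2L, ct)
  if (is_collinear(a) || is_collinear(b))
    stop("degenerate (collinear or coincident) point set")
  h <- crossprod(a, b)              # sum_i a_i b_i^T
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- c(1, 1, d)
  rot <- sv$v %*% diag(s) %*% t(sv$u)
  e2 <- sum(a * a) + sum(b * b) - 2 * sum(sv$d * s)
  list(rotation = rot,
       translation = as.numeric(ct - rot %*% cm),
       rmsd = sqrt(max(e2, 0) / n))
}

## TRUE when centered points span < 2 dimensions (within tolerance).
is_collinear <- function(centered, tol = 1e-8) {
  d <- svd(centered, nu = 0, nv = 0)$d
  d[2] <= tol * max(d[1], 1)
}
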