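# Small numeric helpers shared across modules.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation formula. `axis` need not be normalized.
#'
#' @param axis numeric(3) rotation axis.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero length")
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Convert a Rodrigues vector to a rotation matrix
#'
#' The vector's direction is the rotation axis and its norm the angle in
#' radians; the zero vector maps to the identity.
#'
#' @param rvec numeric(3) Rodrigues rotation vector.
#' @return 3x3 rotation matrix.
#' @export
rodrigues_to_matrix <- function(rvec) {
  stopifnot(length(rvec) == 3)
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-12) return(diag(3))
  rotation_about(rvec, theta)
}

#' Convert a rotation matrix to a Rodrigues vector
#'
#' @param R 3x3 rotation matrix.
#' @return numeric(3) rotation vector (radians).
#' @export
matrix_to_rodrigues <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near 180 degrees: extract axis from R + I
    B <- (R + diag(3)) / 2
    a <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonals using the largest component
    i <- which.max(a)
    if (i == 1) { a[2] <- B[1, 2] / a[1]; a[3] <- B[1, 3] / a[1] }
    if (i == 2) { a[1] <- B[1, 2] / a[2]; a[3] <- B[2, 3] / a[2] }
    if (i == 3) { a[1] <- B[1, 3] / a[3]; a[2] <- B[2, 3] / a[3] }
    return(a / sqrt(sum(a^2)) * theta)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(theta)) * theta
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}

# Euclidean norms of the rows of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m^2))

rmse <- function(x) sqrt(mean(x^2))

#' Rigid alignment of two point sets (Kabsch)
#'
#' Least-squares rotation R and translation t such that R %*% t(from) + t
#' approximates t(to).
#'
#' @param from,to n x 3 matrices of corresponding points (n >= 3).
#' @return list with `rotation` (3x3) and `translation` (numeric(3)).
#' @keywords internal
kabsch <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), nrow(from) >= 3)
  cf <- colMeans(from); ct <- colMeans(to)
  H <- crossprod(sweep(from, 2, cf), sweep(to, 2, ct))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(ct - R %*% cf))
}
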