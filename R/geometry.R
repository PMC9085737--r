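# Rigid-body geometry: Kabsch superposition and helpers.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, via SVD of the cross-covariance matrix with the
#' usual determinant correction so the rotation is never a reflection.
#'
#' @param P,Q Numeric n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   and `rmsd` (Angstrom). The fitted coordinates are
#'   `P %*% rotation + translation` (row-vector convention).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (ncol(P) != 3 || ncol(Q) != 3) stop("coordinate matrices must be n x 3")
  n <- nrow(P)
  if (n != nrow(Q)) stop("P and Q must contain the same number of points")
  if (n < 3) stop("at least 3 point pairs are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1e-12))
    stop("degenerate (collinear) input: rotation is not uniquely defined")
  C <- crossprod(Pc, Qc)
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - cp %*% R), rmsd = rmsd)
}

#' Apply a rigid motion to coordinates
#'
#' @param X n x 3 coordinate matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 vector.
#' @return Transformed n x 3 matrix (`X %*% rotation` then shifted).
#' @export
rigid_transform <- function(X, rotation, translation = c(0, 0, 0)) {
  sweep(as.matrix(X) %*% rotation, 2, -translation)
}

#' Rotation matrix from z-y-x Euler angles (radians)
#'
#' @param a,b,g Rotations about z, y and x respectively.
#' @return 3 x 3 proper rotation matrix.
#' @export
euler_rotation <- function(a, b, g) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), -sin(g), 0, sin(g), cos(g)), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
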