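# Rigid-body and internal-coordinate geometry primitives.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

unit <- function(a) a / vnorm(a)

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place a new atom D given positions A, B, C, the C-D bond length, the
# B-C-D bond angle (degrees) and the A-B-C-D torsion (degrees). NeRF
# construction used by the synthetic backbone builder.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  # sign chosen so dihedral(a, b, c, result) == torsion_deg
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal C-beta position from backbone N, CA, C (standard constant recipe).
reconstruct_cbeta <- function(n, ca, c) {
  b <- ca - n; cc <- c - ca
  a <- vcross(b, cc)
  ca - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD of point
#' set `B` onto point set `A` (paired rows). Reflections are corrected so
#' the rotation determinant is +1.
#'
#' @param A,B Matrices of paired xyz coordinates (n x 3, n >= 3).
#' @return An object of class `superposition`: `rotation` (3 x 3, applied on
#'   the right to row vectors), `translation` (length 3), `rmsd`, and
#'   `core_set` (row indices used in the fit).
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B) || ncol(A) != 3L || ncol(B) != 3L) {
    abort_domain("A and B must be paired n x 3 coordinate matrices")
  }
  if (nrow(A) < 3L) abort_domain("at least 3 paired points are required for superposition")
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  # collinearity check: second singular value must be non-negligible
  svA <- svd(Ac)$d; svB <- svd(Bc)$d
  if (svA[2] < 1e-8 * max(svA[1], 1) || svB[2] < 1e-8 * max(svB[1], 1)) {
    abort_domain("degenerate (collinear) point set; superposition is ill-defined")
  }
  H <- crossprod(Bc, Ac)              # 3 x 3
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  transl <- cA - as.numeric(cB %*% R)
  Bt <- sweep(B %*% R, 2, transl, `+`)
  rmsd <- sqrt(mean(rowSums((A - Bt)^2)))
  structure(
    list(rotation = R, translation = transl, rmsd = rmsd,
         core_set = seq_len(nrow(A))),
    class = "superposition"
  )
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition` from [kabsch_superpose()].
#' @param coords n x 3 coordinate matrix (in the frame of the `B` argument).
#' @return Transformed n x 3 matrix in the `A` frame.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, `+`)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.3f A over %d points\n", x$rmsd, length(x$core_set)))
  invisible(x)
}

# Random proper rotation matrix (QR of a Gaussian matrix, det corrected).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Rigid-transform a structure_model in place (used by tests and fixtures).
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% rotation, 2, translation, `+`)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model$atoms$line <- NA_character_  # coordinates no longer match raw records
  model
}
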