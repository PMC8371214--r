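# small numerical helpers shared across modules

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula for the 3x3 matrix rotating by `angle` (radians,
#' right-handed) about the direction `axis`.
#'
#' @param axis numeric length-3 direction (need not be unit length).
#' @param angle rotation angle in radians.
#' @return 3x3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero length")
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Golden-ratio (Fibonacci) spherical direction grid
#'
#' Quasi-uniform unit directions on the sphere generated from the golden
#' ratio, as used for orientational averaging of scattering amplitudes.
#'
#' @param n number of directions (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# sin(x)/x with the x -> 0 limit
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation R and translation t minimizing ||(P R + t) - Q||^2
#' over paired coordinate sets (rows are points). No scaling or reflection.
#'
#' @param P n x 3 matrix of mobile coordinates.
#' @param Q n x 3 matrix of target coordinates.
#' @return list with `R` (3x3), `t` (length 3), and `rmsd` after fitting.
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- cq - as.vector(cp %*% R)
  fitted <- sweep(P %*% R, 2, t, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

# weighted radius of gyration of a coordinate matrix (rows = points)
coord_rg <- function(xyz, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(xyz))
  w <- w / sum(w)
  ctr <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
}
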