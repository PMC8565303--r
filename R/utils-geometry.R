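# Small 3D geometry helpers shared across modules.  All coordinates are
# Angstrom; all rotation matrices act on column vectors.

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

#' Angle between two vectors
#'
#' Numerically stable angle via atan2 of the cross/dot decomposition,
#' returned in degrees in [0, 180].
#'
#' @param a,b numeric 3-vectors (need not be unit length).
#' @return angle in degrees.
#' @export
angle_between <- function(a, b) {
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  atan2(sqrt(sum(cr^2)), sum(a * b)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation; positive angles follow the right-hand rule about
#' \code{axis}.
#'
#' @param axis numeric 3-vector (normalized internally).
#' @param theta_deg rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, theta_deg) {
  u <- unit_vec(axis)
  th <- theta_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Random rigid motion
#'
#' Draws a uniformly random rotation (QR of a Gaussian matrix, determinant
#' fixed to +1) and a translation with entries in [-50, 50] Angstrom.
#' Deterministic given the current RNG state.
#'
#' @return list with elements \code{R} (3x3) and \code{t} (3-vector).
#' @keywords internal
#' @export
random_rigid_motion <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  R <- R %*% diag(d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::runif(3, -50, 50))
}

#' Apply a rigid motion to a coordinate matrix
#'
#' @param xyz n x 3 coordinate matrix, Angstrom.
#' @param motion list with rotation \code{R} and translation \code{t}.
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% t(motion$R), 2, motion$t, `+`)
}

## Gram-Schmidt: make b orthonormal to unit vector a
orthonormalize_to <- function(b, a) {
  unit_vec(b - sum(b * a) * a)
}

## least-squares direction through an n x 3 point set (first principal axis),
## unoriented
fit_line_direction <- function(xyz) {
  if (nrow(xyz) < 2) stop("need >= 2 points to fit a direction", call. = FALSE)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  sv$v[, 1]
}
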