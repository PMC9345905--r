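# Minimal 3-D rotation helpers. Orientations are carried as rotation vectors
# (axis * angle, rad) so the inverse-kinematics state stays a plain numeric
# vector; conversion uses the Rodrigues formula.

#' Rotation matrix about an arbitrary unit axis
#'
#' @param axis unit 3-vector.
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  K <- skew3(a)
  diag(3) * ct + st * K + (1 - ct) * (a %o% a)
}

#' Rotation vector to rotation matrix (Rodrigues)
#' @param e rotation vector (axis * angle, rad).
#' @keywords internal
rotvec_to_R <- function(e) {
  th <- sqrt(sum(e^2))
  if (th < 1e-12) return(diag(3))
  rot_axis(e / th, th)
}

#' Rotation matrix to rotation vector
#' @param R 3x3 rotation matrix.
#' @keywords internal
R_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near pi: extract axis from R + I
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonal terms
    i <- which.max(ax)
    if (i == 1) ax <- c(ax[1], B[1, 2] / ax[1], B[1, 3] / ax[1])
    if (i == 2) ax <- c(B[1, 2] / ax[2], ax[2], B[2, 3] / ax[2])
    if (i == 3) ax <- c(B[1, 3] / ax[3], B[2, 3] / ax[3], ax[3])
    ax <- ax / sqrt(sum(ax^2))
    return(ax * th)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}

#' Right Jacobian of the SO(3) exponential map
#'
#' For a rotation vector e, relates a perturbation de to the body-frame
#' rotation increment: R(e + de) ~ R(e) exp([Jr(e) de]x). Used for analytic
#' derivatives of world points with respect to the carpal orientation.
#' @param e rotation vector.
#' @keywords internal
rotvec_right_jacobian <- function(e) {
  th <- sqrt(sum(e^2))
  A <- skew3(e)
  if (th < 1e-8) return(diag(3) - A / 2 + (A %*% A) / 6)
  diag(3) - ((1 - cos(th)) / th^2) * A + ((th - sin(th)) / th^3) * (A %*% A)
}

#' Skew-symmetric cross-product matrix S(r), so S(r) %*% f == r x f
#' @param r 3-vector.
#' @keywords internal
skew3 <- function(r) {
  matrix(c(0, r[3], -r[2],
           -r[3], 0, r[1],
           r[2], -r[1], 0), 3, 3)
}

#' Cross product of two 3-vectors
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Normalize a vector to unit length
#' @keywords internal
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}
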