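#' Elementary rotation matrices
#'
#' Right-handed rotation of a vector about a coordinate axis by `angle_rad`.
#' Used to build joint and cup orientations; all frames in this package are
#' right-handed with pelvis axes x anterior, y superior, z lateral (right hip).
#'
#' @param angle_rad rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(angle_rad) {
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(angle_rad) {
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(angle_rad) {
  c_ <- cos(angle_rad); s_ <- sin(angle_rad)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from a rotation vector
#'
#' Rodrigues' formula; the rotation vector points along the axis with length
#' equal to the angle in radians.  Small angles (< 1e-12) return identity.
#'
#' @param w numeric length-3 rotation vector (rad).
#' @return 3x3 rotation matrix.
#' @export
rotmat_from_rotvec <- function(w) {
  stopifnot(length(w) == 3, all(is.finite(w)))
  theta <- sqrt(sum(w^2))
  if (theta < 1e-12) return(diag(3))
  a <- w / theta
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation vector from a rotation matrix
#'
#' Inverse of [rotmat_from_rotvec()]; robust near zero angle (series
#' expansion) and near pi (axis from the symmetric part).
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 rotation vector (rad).
#' @export
rotvec_from_rotmat <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- sum(diag(R))
  cos_t <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cos_t)
  if (theta < 1e-8) {
    # first-order: R ~ I + [w]_x
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (theta > pi - 1e-6) {
    # axis from R + I (rank-1 up to scale)
    B <- (R + diag(3)) / 2
    d <- sqrt(pmax(diag(B), 0))
    k <- which.max(d)
    axis <- B[, k] / d[k]
    axis <- axis / sqrt(sum(axis^2))
    # fix sign from the skew part where possible
    s <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sum(s * axis) < 0) axis <- -axis
    return(axis * theta)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

#' Cup orientation transform (pelvis frame to cup frame)
#'
#' Builds the rotation operator mapping pelvis-frame vectors into the
#' acetabular-cup frame for a right hip.  Radiographic convention: starting
#' from a cup whose pole axis is the pelvis superior axis, the cup is first
#' inclined about the anterior (x) axis so the pole tilts medially by
#' `inclination_deg`, then anteverted about the superior (y) axis by
#' `anteversion_deg` so the pole tips anteriorly.  In the returned cup frame
#' the third axis (z) is the cup pole axis (pointing from the cup centre into
#' the dome).
#'
#' @param inclination_deg cup inclination in degrees, in \[0, 90).
#' @param anteversion_deg cup anteversion in degrees, in \[0, 90).
#' @return 3x3 orthonormal matrix `Q`; `v_cup = Q %*% v_pelvis`.
#' @examples
#' Q <- cup_orientation_transform(40, 15)
#' crossprod(Q)  # identity
#' @export
cup_orientation_transform <- function(inclination_deg, anteversion_deg) {
  stopifnot(inclination_deg >= 0, inclination_deg < 90,
            anteversion_deg >= 0, anteversion_deg < 90)
  inc <- inclination_deg * pi / 180
  av <- anteversion_deg * pi / 180
  # initial cup axes in pelvis coords: x_c = z_p, y_c = x_p, z_c = y_p (pole)
  C0 <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  # inclination: rotate about pelvis x by -inc (pole tilts toward -z, medial);
  # anteversion: rotate about pelvis y by -av (pole tips toward +x, anterior)
  C <- rot_y(-av) %*% rot_x(-inc) %*% C0
  t(C)
}

#' Cup pole axis in pelvis coordinates
#' @param Q transform from [cup_orientation_transform()].
#' @return unit length-3 vector.
#' @keywords internal
cup_pole_pelvis <- function(Q) as.numeric(t(Q) %*% c(0, 0, 1))
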