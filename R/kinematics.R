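#' Per-step head rotation increments in the cup frame
#'
#' Builds the femoral-head orientation at each gait sample from the three
#' joint-angle channels (Euler sequence flexion about the lateral z axis,
#' then abduction about the anterior x axis, then internal rotation about
#' the superior y axis, composed in the pelvis frame) and returns the
#' per-step rotation vectors of the head relative to the pelvis, expressed
#' in the cup frame.  Over a closed (periodic) cycle the increments sum to
#' approximately zero.
#'
#' @param gait_cycle a `gait_cycle`.
#' @param cup_transform 3x3 matrix from [cup_orientation_transform()].
#' @return (n_samples - 1) x 3 matrix of rotation vectors (rad, cup frame).
#' @export
head_rotation_increments <- function(gait_cycle, cup_transform) {
  stopifnot(inherits(gait_cycle, "gait_cycle"), gait_cycle$n_samples >= 2)
  ang <- cbind(gait_cycle$flexion_extension, gait_cycle$abduction_adduction,
               gait_cycle$internal_external_rotation) * pi / 180
  if (any(!is.finite(ang))) stop("joint angles contain NaN or Inf")
  n <- nrow(ang)
  closed <- max(abs(ang[1, ] - ang[n, ])) < 1e-9
  if (!closed) warning("gait cycle is not periodic; increments will not sum to zero")
  Rs <- lapply(seq_len(n), function(i)
    rot_z(ang[i, 1]) %*% rot_x(ang[i, 2]) %*% rot_y(ang[i, 3]))
  W <- matrix(0, n - 1L, 3L)
  for (i in seq_len(n - 1L)) {
    w_pelvis <- rotvec_from_rotmat(Rs[[i + 1L]] %*% t(Rs[[i]]))
    W[i, ] <- as.numeric(cup_transform %*% w_pelvis)
  }
  W
}

#' Partition a head rotation increment between the two articulations
#'
#' Conventional cups: the insert is fixed in the shell, so the whole
#' increment slides at the single (small) articulation.  Dual-mobility
#' cups: a quasi-static friction-torque rule decides which bearing moves —
#' the articulation with the lower resisting torque `T = mu * R_eff * Fn`
#' (Fn = normal-load integral of its contact state) rotates, which with
#' equal transmitted loads is the small articulation (smaller radius).  The
#' large articulation receives rotation only when the accumulated
#' head-liner angle exceeds the engagement threshold `theta_lim_deg` (the
#' surrogate for the third articulation, where neck-chamfer contact drives
#' the mobile liner): the excess beyond the threshold rotates the liner.
#' Small and large increments sum exactly to the total.
#'
#' @param total_increment length-3 rotation vector (rad, cup frame) of the
#'   head relative to the shell for this step.
#' @param small_state,large_state `contact_state`s of the two articulations
#'   (`large_state = NULL` for conventional cups).
#' @param spec an `implant_spec`.
#' @param partition_params list with `theta_lim_deg` (default 25) and `mu`
#'   (default 0.01).
#' @param prev the `motion_increment` of the previous step (or `NULL` at
#'   cycle start), carrying the accumulated head-liner and liner
#'   orientations.
#' @return list of class `motion_increment`: `small`, `large` (rotation
#'   vectors, rad), `rel_orientation` (3x3 head-relative-to-liner),
#'   `liner_orientation` (3x3 liner-relative-to-shell), `engaged` (logical).
#' @export
partition_motion <- function(total_increment, small_state, large_state, spec,
                             partition_params = list(theta_lim_deg = 25, mu = 0.01),
                             prev = NULL) {
  stopifnot(inherits(spec, "implant_spec"), length(total_increment) == 3)
  if (is.null(small_state))
    stop("small-articulation contact state is required")
  rel <- if (is.null(prev)) diag(3) else prev$rel_orientation
  liner <- if (is.null(prev)) diag(3) else prev$liner_orientation
  out <- function(w_s, w_l, rel, liner, engaged) {
    structure(list(small = w_s, large = w_l, rel_orientation = rel,
                   liner_orientation = liner, engaged = engaged),
              class = "motion_increment")
  }
  if (!spec$is_dual_mobility)
    return(out(total_increment, c(0, 0, 0),
               rotmat_from_rotvec(total_increment) %*% rel, liner, FALSE))
  if (is.null(large_state))
    stop("dual-mobility partition requires the large-articulation contact state")

  mu <- partition_params$mu
  radii <- articulation_radii(spec)
  t_small <- mu * radii$small * small_state$normal_load_integral
  t_large <- mu * radii$large * large_state$normal_load_integral
  if (t_large < t_small) {
    # liner slides at the large articulation; head-liner pair locks
    return(out(c(0, 0, 0), total_increment, rel,
               rotmat_from_rotvec(total_increment) %*% liner, TRUE))
  }
  rel_cand <- rotmat_from_rotvec(total_increment) %*% rel
  w_rel <- rotvec_from_rotmat(rel_cand)
  ang <- sqrt(sum(w_rel^2))
  theta_lim <- partition_params$theta_lim_deg * pi / 180
  if (ang <= theta_lim)
    return(out(total_increment, c(0, 0, 0), rel_cand, liner, FALSE))
  axis <- w_rel / ang
  w_large <- (ang - theta_lim) * axis
  w_small <- total_increment - w_large
  out(w_small, w_large, rotmat_from_rotvec(theta_lim * axis),
      rotmat_from_rotvec(w_large) %*% liner, TRUE)
}

#' Per-node sliding-distance increment for a rotation
#'
#' For a rotation vector `w` (rad) of one body relative to the other across
#' an articulation of radius R, the sliding increment at a node with
#' position `r = R d` from the sphere centre is `|w x r|` (mm).  Nodes on
#' the instantaneous rotation axis do not slide.
#'
#' @param mesh a `surface_mesh`.
#' @param rotation_vector length-3 rotation vector (rad, cup frame).
#' @return numeric vector of per-node sliding increments (mm, >= 0).
#' @export
sliding_field <- function(mesh, rotation_vector) {
  stopifnot(inherits(mesh, "surface_mesh"), length(rotation_vector) == 3)
  r <- mesh$node_directions * mesh$radius
  w <- rotation_vector
  cx <- w[2] * r[, 3] - w[3] * r[, 2]
  cy <- w[3] * r[, 1] - w[1] * r[, 3]
  cz <- w[1] * r[, 2] - w[2] * r[, 1]
  sqrt(cx^2 + cy^2 + cz^2)
}
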