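new_wear_field <- function(mesh, h = numeric(mesh$n_nodes), cycles = 1) {
  structure(list(mesh = mesh, h = h,
                 articulation_tag = mesh$articulation_tag,
                 cycles_represented = cycles),
            class = "wear_field")
}

#' Archard linear-wear increment
#'
#' `dh_i = k_w * p_i * ds_i` with pressure in MPa (N/mm2), sliding in mm and
#' the wear coefficient in mm3 N-1 m-1, so the sliding distance is converted
#' to metres internally and the increment comes out in mm.
#'
#' @param pressure_field per-node pressure (MPa, >= 0).
#' @param sliding_field per-node sliding increment (mm, >= 0).
#' @param k_w wear coefficient (mm3 N-1 m-1).
#' @return per-node wear-depth increment (mm).
#' @examples
#' archard_increment(1, 1000, 10.656e-7)  # 1 MPa over 1 m -> 10.656e-7 mm
#' @export
archard_increment <- function(pressure_field, sliding_field, k_w) {
  if (any(pressure_field < 0)) stop("negative pressure")
  if (any(sliding_field < 0)) stop("negative sliding distance")
  k_w * pressure_field * sliding_field / 1000
}

#' Simulate polyethylene wear over one gait cycle
#'
#' Time-steps the gait cycle on its own sampling grid: at each step the
#' joint reaction force (evaluated at step start, rotated into the cup
#' frame) is balanced by the elastic-foundation contact solver, the head
#' rotation increment is partitioned between the articulations
#' (dual-mobility only), sliding fields are evaluated across the step, and
#' the Archard increment is accumulated per node.  Deterministic given its
#' inputs.
#'
#' @param spec an `implant_spec`.
#' @param patient one cohort row (needs `body_mass`, `jrf_scale` via the
#'   gait cycle only; kept for provenance).
#' @param gait_cycle a `gait_cycle` (pelvis-frame JRF).
#' @param sim_params list: `mesh_edge` (mm, default 0.75), `theta_lim_deg`
#'   (default 25), `mu` (default 0.01), `meshes` (optional pre-built list
#'   `small`/`large` to reuse across patients).
#' @return list of class `cycle_wear`: `small` (and `large` for
#'   dual-mobility) `wear_field`s for one cycle, plus `diagnostics`
#'   (per-step peak pressure and partition fractions).
#' @export
simulate_cycle <- function(spec, patient, gait_cycle,
                           sim_params = list()) {
  stopifnot(inherits(spec, "implant_spec"), inherits(gait_cycle, "gait_cycle"))
  sp <- utils::modifyList(list(mesh_edge = 0.75, theta_lim_deg = 25, mu = 0.01,
                               meshes = NULL), sim_params)
  radii <- articulation_radii(spec)
  meshes <- sp$meshes
  if (is.null(meshes)) {
    meshes <- list(small = build_bearing_mesh(radii$small, sp$mesh_edge, "small"))
    if (spec$is_dual_mobility)
      meshes$large <- build_bearing_mesh(radii$large, sp$mesh_edge, "large")
  }
  Q <- cup_orientation_transform(spec$cup_inclination, spec$cup_anteversion)
  W <- head_rotation_increments(gait_cycle, Q)
  load_cup <- gait_cycle$jrf %*% t(Q)
  k_w <- spec$liner_material$wear_coefficient
  mat <- spec$liner_material
  t_small <- spec$liner_thickness_small

  h_small <- numeric(meshes$small$n_nodes)
  h_large <- if (spec$is_dual_mobility) numeric(meshes$large$n_nodes) else NULL
  n_steps <- nrow(W)
  diag_peak_p <- numeric(n_steps)
  diag_small_frac <- numeric(n_steps)
  prev <- NULL
  pp <- list(theta_lim_deg = sp$theta_lim_deg, mu = sp$mu)
  if (spec$is_dual_mobility) {
    # settle-in: the mobile liner finds its steady orientation within the
    # motion cone before wear is recorded (steady-state assumption); the
    # partition pre-pass needs no pressures, only the torque comparison,
    # for which equal transmitted loads suffice.
    dummy <- structure(list(normal_load_integral = 1), class = "contact_state")
    for (pass in 1:2) for (i in seq_len(n_steps))
      prev <- partition_motion(W[i, ], dummy, dummy, spec, pp, prev)
  }
  for (i in seq_len(n_steps)) {
    load <- load_cup[i, ]
    st_small <- solve_contact(meshes$small, mat, t_small,
                              spec$small_articulation_radial_clearance, load)
    st_large <- NULL
    if (spec$is_dual_mobility)
      st_large <- solve_contact(meshes$large, mat, t_small,
                                spec$large_articulation_radial_clearance, load)
    inc <- partition_motion(W[i, ], st_small, st_large, spec, pp, prev)
    prev <- inc
    ds_small <- sliding_field(meshes$small, inc$small)
    h_small <- h_small + archard_increment(st_small$pressure, ds_small, k_w)
    if (spec$is_dual_mobility && any(inc$large != 0)) {
      ds_large <- sliding_field(meshes$large, inc$large)
      h_large <- h_large + archard_increment(st_large$pressure, ds_large, k_w)
    }
    diag_peak_p[i] <- max(st_small$pressure)
    tot <- sqrt(sum(W[i, ]^2))
    diag_small_frac[i] <- if (tot > 0) sqrt(sum(inc$small^2)) / tot else 1
  }
  out <- list(small = new_wear_field(meshes$small, h_small),
              large = if (spec$is_dual_mobility)
                new_wear_field(meshes$large, h_large) else NULL,
              diagnostics = data.frame(step = seq_len(n_steps),
                                       peak_pressure = diag_peak_p,
                                       small_fraction = diag_small_frac),
              config_id = spec$config_id,
              patient_id = if (!is.null(patient$id)) patient$id else NA_character_)
  class(out) <- "cycle_wear"
  out
}

#' Extrapolate a one-cycle wear field to many cycles
#'
#' Steady-state polyethylene wear is linear in cycle count, so the
#' accumulated depth of a single simulated cycle is scaled by `n_cycles`
#' (1.0 million cycles of level walking approximates one year of normal
#' activity); the geometry is not updated.
#'
#' @param one_cycle_field a `wear_field` (or a `cycle_wear`, in which case
#'   each articulation field is extrapolated).
#' @param n_cycles number of cycles (>= 1).
#' @return object of the same class with depths scaled.
#' @export
extrapolate_wear <- function(one_cycle_field, n_cycles = 1e6) {
  stopifnot(n_cycles >= 1)
  if (inherits(one_cycle_field, "cycle_wear")) {
    one_cycle_field$small <- extrapolate_wear(one_cycle_field$small, n_cycles)
    if (!is.null(one_cycle_field$large))
      one_cycle_field$large <- extrapolate_wear(one_cycle_field$large, n_cycles)
    return(one_cycle_field)
  }
  stopifnot(inherits(one_cycle_field, "wear_field"))
  one_cycle_field$h <- one_cycle_field$h * n_cycles
  one_cycle_field$cycles_represented <-
    one_cycle_field$cycles_represented * n_cycles
  one_cycle_field
}

#' Volumetric wear of a wear field
#'
#' First-order volume difference `V = sum(h_i A_i)` (mm3); valid because
#' wear depths are orders of magnitude smaller than the bearing radius.
#'
#' @param wear_field a `wear_field`.
#' @return volumetric wear in mm3.
#' @export
volumetric_wear <- function(wear_field) {
  stopifnot(inherits(wear_field, "wear_field"))
  sum(wear_field$h * wear_field$mesh$node_areas)
}

#' Linear wear of a wear field (maximum node depth, mm)
#' @param wear_field a `wear_field`.
#' @return maximum wear depth in mm.
#' @export
linear_wear <- function(wear_field) {
  stopifnot(inherits(wear_field, "wear_field"))
  if (!length(wear_field$h)) return(0)
  max(wear_field$h)
}

#' Summarize a (possibly extrapolated) cycle simulation
#'
#' @param cycle_wear a `cycle_wear`.
#' @return one-row data.frame: `patient_id`, `config_id`, `cycles`,
#'   `volumetric_wear` (total, mm3), `v_small`, `v_large`, `linear_wear`
#'   (small-articulation maximum depth, mm).
#' @export
wear_summary <- function(cycle_wear) {
  stopifnot(inherits(cycle_wear, "cycle_wear"))
  v_s <- volumetric_wear(cycle_wear$small)
  v_l <- if (!is.null(cycle_wear$large)) volumetric_wear(cycle_wear$large) else 0
  data.frame(patient_id = cycle_wear$patient_id,
             config_id = cycle_wear$config_id,
             cycles = cycle_wear$small$cycles_represented,
             volumetric_wear = v_s + v_l, v_small = v_s, v_large = v_l,
             linear_wear = linear_wear(cycle_wear$small),
             stringsAsFactors = FALSE)
}
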