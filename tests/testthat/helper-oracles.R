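# Independent oracles used across the suite.  These recompute the physics
# from scratch (dense-grid quadrature, naive loops) and deliberately share
# no code with the package internals beyond the public API they check.

# Axisymmetric elastic-foundation contact on a dense 1D polar grid:
# ring quadrature of p(theta) = min(sig_y, k_f * max(0, e cos(theta) - c))
# with scalar root-finding on the centre offset e.  Returns the offset,
# peak pressure and a function giving the axial force at any offset.
oracle_axisymmetric_contact <- function(R, k_f, sig_y, clearance, load,
                                        d_theta_deg = 0.05) {
  th <- seq(0, pi / 2, by = d_theta_deg * pi / 180)
  dA <- 2 * pi * R^2 * sin(th)          # per unit of theta
  axial_force <- function(e) {
    p <- pmin(sig_y, k_f * pmax(0, e * cos(th) - clearance))
    # trapezoid in theta
    integrand <- p * cos(th) * dA
    sum((integrand[-1] + integrand[-length(th)]) / 2) * diff(th[1:2])
  }
  e <- stats::uniroot(function(e) axial_force(e) - load,
                      c(clearance, clearance + 10), extendInt = "upX",
                      tol = 1e-12)$root
  list(offset = e, peak_pressure = min(sig_y, k_f * (e - clearance)),
       axial_force = axial_force)
}

# Naive brute-force Archard accumulation: explicit double loop over steps
# and nodes, scalar arithmetic only.  Uses the package's contact solver and
# kinematics outputs as inputs (the thing under test is the vectorized
# accumulation in simulate_cycle / volumetric_wear).
oracle_wear_volume <- function(spec, gait, mesh) {
  Q <- cup_orientation_transform(spec$cup_inclination, spec$cup_anteversion)
  W <- head_rotation_increments(gait, Q)
  k_w <- spec$liner_material$wear_coefficient
  R <- mesh$radius
  V <- 0
  h <- numeric(mesh$n_nodes)
  for (i in seq_len(nrow(W))) {
    load <- as.numeric(Q %*% gait$jrf[i, ])
    st <- solve_contact(mesh, spec$liner_material, spec$liner_thickness_small,
                        spec$small_articulation_radial_clearance, load)
    w <- W[i, ]
    for (j in seq_len(mesh$n_nodes)) {
      r <- mesh$node_directions[j, ] * R
      ds <- sqrt(sum(c(w[2] * r[3] - w[3] * r[2],
                       w[3] * r[1] - w[1] * r[3],
                       w[1] * r[2] - w[2] * r[1])^2))
      dh <- k_w * st$pressure[j] * ds / 1000
      h[j] <- h[j] + dh
      V <- V + dh * mesh$node_areas[j]
    }
  }
  list(V = V, h = h)
}

# one default patient + averaged gait, memoised for reuse across files
default_patient_gait <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- sample_cohort(seed = 42)
      g <- synthesize_gait(co[1, ], n_samples = 101)
      cache <<- list(patient = co[1, ], gait = g, cohort = co)
    }
    cache
  }
})

# the control-vs-XLPE cohort study used by the acceptance blocks (heavy:
# 15 patients x 2 dual-mobility constructs), computed once
dm_cohort_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_study(study_config(seed = 42,
                                       configs = c("DM22PE", "DM22XL")))
    cache
  }
})
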