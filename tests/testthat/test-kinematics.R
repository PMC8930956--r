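test_that("rotation increments recover single-axis paths and close over a cycle", {
  pg <- default_patient_gait()
  Q <- cup_orientation_transform(40, 15)
  # constant angles: all increments zero
  g0 <- pg$gait
  g0$flexion_extension[] <- 5; g0$abduction_adduction[] <- -2
  g0$internal_external_rotation[] <- 1
  W0 <- head_rotation_increments(g0, Q)
  expect_identical(max(abs(W0)), 0)
  # pure flexion ramp 0 -> 40 deg: increments share one axis and sum to
  # 40 deg = 0.6981 rad
  gr <- pg$gait
  gr$flexion_extension <- seq(0, 40, length.out = gr$n_samples)
  gr$abduction_adduction[] <- 0; gr$internal_external_rotation[] <- 0
  expect_warning(Wr <- head_rotation_increments(gr, Q), "periodic")
  expect_equal(sum(sqrt(rowSums(Wr^2))), 40 * pi / 180, tolerance = 1e-9)
  axes <- Wr / sqrt(rowSums(Wr^2))
  expect_lt(max(stats::dist(axes)), 1e-9)  # common axis
  # flexion axis is the pelvis lateral axis, mapped to the cup frame
  expect_equal(as.numeric(axes[1, ]), as.numeric(Q %*% c(0, 0, 1)),
               tolerance = 1e-9)
  # closed default cycle: the composed increments return to the start
  # exactly; the rotation-vector sum vanishes to second order (it is small
  # against the ~1.5 rad path length but not zero, by non-commutativity)
  W <- head_rotation_increments(pg$gait, Q)
  R_tot <- Reduce(function(acc, i) rotmat_from_rotvec(W[i, ]) %*% acc,
                  seq_len(nrow(W)), diag(3))
  expect_lt(max(abs(R_tot - diag(3))), 1e-9)
  expect_lt(sqrt(sum(colSums(W)^2)), 0.1)
  # NaN angles rejected
  gn <- pg$gait; gn$flexion_extension[3] <- NaN
  expect_error(head_rotation_increments(gn, Q), "NaN")
})

test_that("per-cycle angular path length matches dense-grid quadrature", {
  pg <- default_patient_gait()
  Q <- cup_orientation_transform(40, 15)
  path_at <- function(n) {
    g <- synthesize_gait(pg$patient, n_samples = n, seed = NULL)
    sum(sqrt(rowSums(head_rotation_increments(g, Q)^2)))
  }
  coarse <- path_at(101)
  dense <- path_at(1001)
  expect_lt(abs(coarse - dense) / dense, 0.001)
})

test_that("sliding fields are the rigid-body arc lengths", {
  m <- build_bearing_mesh(11.1, 0.75)
  ds <- sliding_field(m, c(0, 0, 0.01))  # 0.01 rad about the pole axis
  # pole node does not slide; equator nodes slide R * dtheta = 0.111 mm
  expect_identical(ds[1], 0)
  eq_nodes <- which(abs(m$node_directions[, 3]) < 1e-9)
  expect_gt(length(eq_nodes), 10)
  expect_equal(ds[eq_nodes], rep(0.111, length(eq_nodes)), tolerance = 1e-9)
  expect_true(all(ds >= 0))
  # half-step composition agrees to first order
  set.seed(31)
  w <- stats::rnorm(3) * 0.02
  full <- sliding_field(m, w)
  halves <- sliding_field(m, w / 2) + sliding_field(m, w / 2)
  expect_lt(max(abs(full - halves)), 1e-12)  # same axis: exact additivity
})

test_that("conventional cups put all motion at the single articulation", {
  pg <- default_patient_gait()
  spec <- make_implant_spec("SD22PE")
  dummy <- structure(list(normal_load_integral = 500), class = "contact_state")
  inc <- partition_motion(c(0.01, 0.02, -0.01), dummy, NULL, spec)
  expect_identical(inc$large, c(0, 0, 0))
  expect_identical(inc$small, c(0.01, 0.02, -0.01))
})

test_that("dual-mobility partition follows the torque rule and engagement threshold", {
  spec <- make_implant_spec("DM22PE")
  st <- function(fn) structure(list(normal_load_integral = fn),
                               class = "contact_state")
  pp <- list(theta_lim_deg = 25, mu = 0.01)
  # equal loads: torque mu*F*R is lower at the small articulation
  # (11.1 vs 23 mm radius), so below the threshold all motion stays there
  inc <- partition_motion(c(0.1, 0, 0), st(1000), st(1000), spec, pp)
  expect_identical(inc$large, c(0, 0, 0))
  expect_equal(inc$small, c(0.1, 0, 0))
  # accumulated angle beyond theta_lim: the excess rotates the liner
  prev <- NULL
  total <- 30 * pi / 180
  for (k in 1:10)
    prev <- partition_motion(c(total / 10, 0, 0), st(1000), st(1000), spec,
                             pp, prev)
  large_sum <- total - 25 * pi / 180
  # head-liner angle is pinned at the threshold
  expect_equal(sqrt(sum(rotvec_from_rotmat(prev$rel_orientation)^2)),
               25 * pi / 180, tolerance = 1e-9)
  expect_equal(sqrt(sum(rotvec_from_rotmat(prev$liner_orientation)^2)),
               large_sum, tolerance = 1e-9)
  # conservation: small + large = total at every step
  prev2 <- partition_motion(c(0.3, 0.2, 0), st(1000), st(1000), spec, pp)
  expect_equal(prev2$small + prev2$large, c(0.3, 0.2, 0), tolerance = 1e-12)
  # a lower large-articulation torque (hypothetically) moves the liner
  inc2 <- partition_motion(c(0.05, 0, 0), st(1000), st(1), spec, pp)
  expect_identical(inc2$small, c(0, 0, 0))
  expect_equal(inc2$large, c(0.05, 0, 0))
  expect_error(partition_motion(c(0.1, 0, 0), st(1000), NULL, spec, pp),
               "large-articulation")
})

test_that("motion and wear predominate at the small articulation over a default cycle", {
  pg <- default_patient_gait()
  cw <- simulate_cycle(make_implant_spec("DM22PE"), pg$patient, pg$gait,
                       sim_params = list(mesh_edge = 1.5))
  expect_gt(mean(cw$diagnostics$small_fraction), 0.95)
  v_small <- volumetric_wear(cw$small)
  v_large <- volumetric_wear(cw$large)
  expect_gt(v_small, 0)
  expect_lt(v_large, 0.05 * (v_small + v_large))
})

test_that("per-cycle sliding scales linearly with articulation radius", {
  w <- c(0.004, -0.01, 0.02)
  m1 <- build_bearing_mesh(11.1, 1.0)
  m2 <- build_bearing_mesh(22.2, 1.0)
  s1 <- max(sliding_field(m1, w))
  s2 <- max(sliding_field(m2, w))
  expect_equal(s2 / s1, 2, tolerance = 1e-6)
})
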