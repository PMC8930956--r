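test_that("foundation stiffness follows the confined-layer formula", {
  pe <- material_model("UHMWPE")
  expect_equal(foundation_stiffness(pe, 8),
               500 * 0.55 / (1.45 * 0.10 * 8), tolerance = 1e-12)  # 237.07
  xl <- material_model("XLPE")
  xl$yield_stress <- pe$yield_stress  # isolate E
  xl$poisson_ratio <- 0.45
  expect_equal(foundation_stiffness(xl, 8), 2 * foundation_stiffness(pe, 8))
  # nu = 0 limit: k_f = E / t
  pe0 <- pe; pe0$poisson_ratio <- 0
  expect_equal(foundation_stiffness(pe0, 4), 500 / 4)
  pe5 <- pe; pe5$poisson_ratio <- 0.5
  expect_error(foundation_stiffness(pe5, 8), "incompressible")
  expect_error(foundation_stiffness(material_model("CoCr-rigid"), 8), "rigid")
  expect_error(foundation_stiffness(pe, 0), "thickness")
})

test_that("zero load gives zero pressure and an open gap", {
  m <- build_bearing_mesh(11.1, 1.5)
  st <- solve_contact(m, material_model("UHMWPE"), 11.9, 0.15, c(0, 0, 0))
  expect_identical(sum(st$pressure), 0)
  expect_identical(sum(st$contact), 0L)
  expect_lte(st$penetration_depth, 0)
})

test_that("axial contact matches the dense-grid axisymmetric oracle", {
  m <- build_bearing_mesh(11.1, 0.75)
  pe <- material_model("UHMWPE")
  k_f <- foundation_stiffness(pe, 11.9)
  load <- c(0, 0, 1500)
  st <- solve_contact(m, pe, 11.9, 0.15, load)
  # load balance: full vector residual below 1e-4 relative
  res <- contact_residual(st, m, load)
  expect_lt(sqrt(sum(res^2)), 1e-4 * 1500)
  # peak pressure within 2% of the oracle, located at the load-axis pole
  orc <- oracle_axisymmetric_contact(11.1, k_f, pe$yield_stress, 0.15, 1500)
  expect_lt(abs(max(st$pressure) - orc$peak_pressure) / orc$peak_pressure, 0.02)
  expect_equal(which.max(st$pressure), 1L)  # pole node
  expect_lt(abs(st$penetration_depth - (orc$offset - 0.15)) / orc$offset, 0.02)
})

test_that("the yield cap bounds pressure and enlarges the patch", {
  m <- build_bearing_mesh(11.1, 0.75)
  pe <- material_model("UHMWPE")
  # at sigma_y = 1 MPa the fully-yielded axial capacity is pi R^2 = 387 N,
  # so the capped case is exercised at 300 N
  soft <- pe; soft$yield_stress <- 1
  st <- solve_contact(m, pe, 11.9, 0.15, c(0, 0, 300))
  st_soft <- solve_contact(m, soft, 11.9, 0.15, c(0, 0, 300))
  expect_lte(max(st_soft$pressure), 1 + 1e-9)
  expect_gt(sum(st_soft$contact), sum(st$contact))
  expect_gt(sum(st_soft$pressure == 1), 5)  # finite capped region
  k_f <- foundation_stiffness(pe, 11.9)
  orc <- oracle_axisymmetric_contact(11.1, k_f, 1, 0.15, 300)
  expect_equal(max(st_soft$pressure), orc$peak_pressure, tolerance = 1e-9)
  res <- contact_residual(st_soft, m, c(0, 0, 300))
  expect_lt(sqrt(sum(res^2)), 1e-4 * 300)
  # far beyond capacity: rejected as unsupportable
  expect_error(solve_contact(m, soft, 11.9, 0.15, c(0, 0, 5000)),
               "unsupportable")
})

test_that("oblique loads balance and match the rotated oracle", {
  m <- build_bearing_mesh(11.1, 0.75)
  pe <- material_model("UHMWPE")
  k_f <- foundation_stiffness(pe, 11.9)
  u <- c(sin(30 * pi / 180), 0, cos(30 * pi / 180))
  load <- 1800 * u
  st <- solve_contact(m, pe, 11.9, 0.15, load)
  res <- contact_residual(st, m, load)
  expect_lt(sqrt(sum(res^2)), 1e-4 * 1800)
  # patch centred within a few degrees of the load axis and the oracle
  # peak applies because the patch stays well inside the hemisphere
  orc <- oracle_axisymmetric_contact(11.1, k_f, pe$yield_stress, 0.15, 1800)
  expect_lt(abs(max(st$pressure) - orc$peak_pressure) / orc$peak_pressure, 0.02)
  peak_dir <- m$node_directions[which.max(st$pressure), ]
  expect_gt(sum(peak_dir * u), cos(5 * pi / 180))
})

test_that("monotonicity and stiffness scaling behave as the foundation model predicts", {
  m <- build_bearing_mesh(11.1, 1.0)
  pe <- material_model("UHMWPE")
  loads <- c(500, 1000, 2000)
  sts <- lapply(loads, function(L) solve_contact(m, pe, 11.9, 0.15, c(0, 0, L)))
  deltas <- vapply(sts, `[[`, 0, "penetration_depth")
  peaks <- vapply(sts, function(s) max(s$pressure), 0)
  patch <- vapply(sts, function(s) sum(s$contact), 0L)
  expect_true(all(diff(deltas) > 0))
  expect_true(all(diff(peaks) > 0))
  expect_true(all(diff(patch) > 0))
  # doubling E halves the penetration pre-yield (exact in the conformal
  # clearance -> 0 limit, where interference ~ load / stiffness); the load
  # integral of the pressure along the axis is unchanged
  stiff <- pe; stiff$elastic_modulus <- 1000; stiff$yield_stress <- 1e6
  soft2 <- pe; soft2$yield_stress <- 1e6
  s1 <- solve_contact(m, soft2, 11.9, 0, c(0, 0, 800))
  s2 <- solve_contact(m, stiff, 11.9, 0, c(0, 0, 800))
  expect_equal(s2$penetration_depth, s1$penetration_depth / 2,
               tolerance = 1e-6)
  # at finite clearance the stiffer liner still penetrates less
  f1 <- solve_contact(m, soft2, 11.9, 0.15, c(0, 0, 800))
  f2 <- solve_contact(m, stiff, 11.9, 0.15, c(0, 0, 800))
  expect_lt(f2$penetration_depth, f1$penetration_depth)
  expect_equal(sum(s1$pressure * m$node_areas * m$node_directions[, 3]), 800,
               tolerance = 1e-6)
  expect_equal(sum(s2$pressure * m$node_areas * m$node_directions[, 3]), 800,
               tolerance = 1e-6)
})

test_that("the residual probe reports equilibrium errors linearly", {
  m <- build_bearing_mesh(11.1, 1.5)
  pe <- material_model("UHMWPE")
  load <- c(100, 0, 1200)
  st <- solve_contact(m, pe, 11.9, 0.15, load)
  expect_lt(sqrt(sum(contact_residual(st, m, load)^2)), 1e-4 * sqrt(sum(load^2)))
  # zero-pressure state against zero load: zero residual
  st0 <- solve_contact(m, pe, 11.9, 0.15, c(0, 0, 0))
  expect_identical(contact_residual(st0, m, c(0, 0, 0)), c(0, 0, 0))
  # probing a converged state with a doubled load returns ~ -load
  r2 <- contact_residual(st, m, 2 * load)
  expect_equal(r2, -load, tolerance = 1e-4 * sqrt(sum(load^2)))
})
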