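test_that("synthesized cycles are periodic, load-scaled and physiological", {
  pg <- default_patient_gait()
  co <- pg$cohort
  for (i in c(1, 5, 9, 15)) {
    g <- synthesize_gait(co[i, ], n_samples = 101, seed = 10 + i)
    # periodicity: first sample equals last on every channel
    expect_lt(abs(g$flexion_extension[1] - g$flexion_extension[101]), 1e-9)
    expect_lt(abs(g$abduction_adduction[1] - g$abduction_adduction[101]), 1e-9)
    expect_lt(abs(g$internal_external_rotation[1] -
                    g$internal_external_rotation[101]), 1e-9)
    expect_lt(max(abs(g$jrf[1, ] - g$jrf[101, ])), 1e-6)
    # peak load between 2 and 4 body weights
    bw <- co$body_mass[i] * 9.81
    peak <- max(sqrt(rowSums(g$jrf^2)))
    expect_gt(peak / bw, 2); expect_lt(peak / bw, 4)
    # summed per-channel angular path length in [1.0, 2.5] rad
    path <- (sum(abs(diff(g$flexion_extension))) +
             sum(abs(diff(g$abduction_adduction))) +
             sum(abs(diff(g$internal_external_rotation)))) * pi / 180
    expect_gt(path, 1.0); expect_lt(path, 2.5)
  }
})

test_that("JRF scales exactly linearly with body mass", {
  pg <- default_patient_gait()
  p1 <- pg$patient
  p2 <- p1; p2$body_mass <- 2 * p1$body_mass
  g1 <- synthesize_gait(p1, n_samples = 51, seed = 3)
  g2 <- synthesize_gait(p2, n_samples = 51, seed = 3)
  expect_equal(g2$jrf, 2 * g1$jrf)
  expect_identical(g2$flexion_extension, g1$flexion_extension)
})

test_that("zero-amplitude templates give constant angles and zero wear", {
  pg <- default_patient_gait()
  zero <- list(mean = 0, c1 = 0, s1 = 0, c2 = 0, s2 = 0)
  gp <- default_gait_params(overrides = list(gait = list(angles_deg = list(
    flexion = zero, abduction = zero, rotation = zero))))
  g <- synthesize_gait(pg$patient, gp, n_samples = 31)
  expect_equal(diff(range(g$flexion_extension)), 0)
  cw <- simulate_cycle(make_implant_spec("SD22PE"), pg$patient, g,
                       sim_params = list(mesh_edge = 2))
  expect_identical(max(cw$small$h), 0)
  expect_identical(volumetric_wear(cw$small), 0)
})

test_that("cycle averaging reduces variance and preserves symmetric templates", {
  pg <- default_patient_gait()
  cycles <- lapply(1:11, function(k)
    synthesize_gait(pg$patient, n_samples = 51, seed = 100 + k))
  avg <- average_cycles(cycles)
  per_cycle_var <- mean(vapply(cycles, function(cy)
    stats::var(cy$flexion_extension), numeric(1)))
  across <- vapply(cycles, function(cy) cy$flexion_extension[13], numeric(1))
  expect_lt(stats::var(vapply(1:51, function(j)
    mean(vapply(cycles, function(cy) cy$flexion_extension[j], numeric(1))) -
      avg$flexion_extension[j], numeric(1))), 1e-20)  # mean is pointwise
  expect_gt(stats::var(across), 0)
  # single-cycle averaging is the identity
  expect_equal(average_cycles(cycles[1]), cycles[[1]])
  # mirror perturbations about a template cancel exactly
  base <- synthesize_gait(pg$patient, n_samples = 51, seed = NULL)
  up <- base; up$flexion_extension <- base$flexion_extension + 2
  dn <- base; dn$flexion_extension <- base$flexion_extension - 2
  expect_equal(average_cycles(list(up, dn)), base)
  # mismatched grids are rejected
  g2 <- synthesize_gait(pg$patient, n_samples = 41, seed = 1)
  expect_error(average_cycles(list(cycles[[1]], g2)), "common time grid")
})

test_that("the eleven-cycle patient average has lower channel variance than single cycles", {
  pg <- default_patient_gait()
  cycles <- lapply(1:11, function(k)
    synthesize_gait(pg$patient, n_samples = 51, seed = 200 + k))
  avg <- average_cycles(cycles)
  # variance of the mean cycle's deviation from the template is below the
  # mean squared deviation of individual cycles
  base <- synthesize_gait(pg$patient, n_samples = 51, seed = NULL)
  dev_single <- mean(vapply(cycles, function(cy)
    mean((cy$flexion_extension - base$flexion_extension)^2), numeric(1)))
  dev_avg <- mean((avg$flexion_extension - base$flexion_extension)^2)
  expect_lt(dev_avg, dev_single)
})

test_that("gait CSV round-trips and reports malformed input precisely", {
  pg <- default_patient_gait()
  g <- synthesize_gait(pg$patient, n_samples = 33, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_gait_csv(g, path)
  g2 <- read_gait_csv(path)
  expect_lt(max(abs(g2$jrf - g$jrf)), 1e-9)
  expect_lt(max(abs(g2$flexion_extension - g$flexion_extension)), 1e-9)
  expect_lt(max(abs(g2$time - g$time)), 1e-9)
  # missing column
  df <- utils::read.csv(path)
  utils::write.csv(df[, setdiff(names(df), "jrf_z_N")], path, row.names = FALSE)
  expect_error(read_gait_csv(path), "jrf_z_N")
  # non-monotone time names the offending row
  write_gait_csv(g, path)
  df <- utils::read.csv(path)
  df$time_s[5] <- df$time_s[7]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_gait_csv(path), "row 6")
  # non-numeric cell names the line
  write_gait_csv(g, path)
  lines <- readLines(path)
  lines[4] <- sub("^[^,]*", "oops", lines[4])
  writeLines(lines, path)
  expect_error(read_gait_csv(path), "line")
})
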