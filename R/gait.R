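# evaluate one sum-of-harmonics angle channel (deg) on normalized time t
eval_angle_channel <- function(ch, t, amp_mult = 1) {
  ch$mean + amp_mult * (ch$c1 * cos(2 * pi * t) + ch$s1 * sin(2 * pi * t) +
                        ch$c2 * cos(4 * pi * t) + ch$s2 * sin(4 * pi * t))
}

# double-peaked stance-phase load profile in body weights
eval_jrf_bw <- function(jp, t, peak_mult = 1) {
  x <- t / jp$stance_fraction
  beta <- jp$double_peak_depth
  f <- ifelse(x < 1, sin(pi * pmax(pmin(x, 1), 0)) * (1 + beta * cos(2 * pi * x)), 0)
  xg <- seq(0, 1, length.out = 2001)
  f_max <- max(sin(pi * xg) * (1 + beta * cos(2 * pi * xg)))
  peak <- jp$swing_bw + peak_mult * (jp$peak_bw - jp$swing_bw)
  jp$swing_bw + (peak - jp$swing_bw) * f / f_max
}

# unit load direction in the pelvis frame over the cycle (n x 3)
eval_jrf_direction <- function(dirp, t) {
  x <- dirp$anterior_mean + dirp$anterior_sway * cos(2 * pi * t)
  y <- rep(1, length(t))
  z <- rep(dirp$medial, length(t))
  m <- cbind(x, y, z)
  m / sqrt(rowSums(m^2))
}

new_gait_cycle <- function(time, flex, abd, rot, jrf, duration) {
  structure(list(n_samples = length(time), time = time,
                 flexion_extension = flex, abduction_adduction = abd,
                 internal_external_rotation = rot, jrf = jrf,
                 cycle_duration = duration),
            class = "gait_cycle")
}

#' Synthesize one level-walking gait cycle for a patient
#'
#' Evaluates the configured waveform templates on a uniform normalized time
#' grid: three periodic hip-angle channels (flexion/extension dominant) and
#' a joint-reaction-force vector with a double-peaked stance phase and
#' near-zero swing load, in the pelvis frame.  The JRF magnitude is
#' `body weight x jrf_scale x` template, so it scales exactly linearly with
#' body mass.  `seed` drives a small per-cycle perturbation of the angle
#' amplitudes and JRF peak (multipliers clamped to two SDs), emulating
#' stride-to-stride variability.
#'
#' @param patient one row of a [sample_cohort()] data.frame (or a list with
#'   `body_mass` and `jrf_scale`).
#' @param gait_params [default_gait_params()] list.
#' @param n_samples samples across the cycle including the repeated
#'   endpoint (>= 16).
#' @param seed integer seed for the per-cycle perturbation; `NULL` for the
#'   unperturbed template.
#' @return object of class `gait_cycle`: normalized `time` on \[0, 1\]
#'   (first = last sample), angle channels in degrees, `jrf` (n x 3, N,
#'   pelvis frame), `cycle_duration` (s).
#' @export
synthesize_gait <- function(patient, gait_params = default_gait_params(),
                            n_samples = 101L, seed = NULL) {
  if (n_samples < 16) stop("n_samples must be >= 16")
  g <- gait_params$gait
  v <- g$variability
  clamp <- function(x, sd) pmax(1 - 2 * sd, pmin(1 + 2 * sd, x))
  if (is.null(seed)) {
    am <- c(1, 1, 1); jm <- 1
  } else {
    pert <- with_seed(seed, stats::rnorm(4))
    am <- clamp(1 + v$cycle_amp_sd * pert[1:3], v$cycle_amp_sd)
    jm <- clamp(1 + v$cycle_jrf_sd * pert[4], v$cycle_jrf_sd)
  }
  pm <- if (is.null(gait_params$patient_amp_mult)) 1 else gait_params$patient_amp_mult
  t <- seq(0, 1, length.out = n_samples)
  flex <- eval_angle_channel(g$angles_deg$flexion, t, pm * am[1])
  abd <- eval_angle_channel(g$angles_deg$abduction, t, pm * am[2])
  rot <- eval_angle_channel(g$angles_deg$rotation, t, pm * am[3])
  bw <- patient$body_mass * 9.81
  mag <- bw * patient$jrf_scale * eval_jrf_bw(g$jrf, t, jm)
  jrf <- eval_jrf_direction(g$jrf$direction, t) * mag
  new_gait_cycle(t, flex, abd, rot, jrf, g$cycle_duration_s)
}

#' Average several gait cycles on a common time grid
#'
#' Pointwise mean of all channels (angles and JRF components); periodicity
#' is preserved.  Mirrors the study protocol of averaging eleven walking
#' cycles into a single representative cycle per patient.
#'
#' @param cycles list of `gait_cycle` objects on identical time grids.
#' @return a `gait_cycle`.
#' @export
average_cycles <- function(cycles) {
  if (!length(cycles)) stop("need at least one cycle")
  stopifnot(all(vapply(cycles, inherits, TRUE, "gait_cycle")))
  t0 <- cycles[[1]]$time
  for (cy in cycles) {
    if (length(cy$time) != length(t0) || max(abs(cy$time - t0)) > 1e-12)
      stop("cycles are not on a common time grid")
  }
  avg <- function(field) Reduce(`+`, lapply(cycles, `[[`, field)) / length(cycles)
  new_gait_cycle(t0, avg("flexion_extension"), avg("abduction_adduction"),
                 avg("internal_external_rotation"), avg("jrf"),
                 mean(vapply(cycles, `[[`, 0, "cycle_duration")))
}

#' Read / write a gait cycle as CSV
#'
#' Schema: header `time_s, flex_deg, abd_deg, rot_deg, jrf_x_N, jrf_y_N,
#' jrf_z_N`; time in seconds, strictly increasing from 0.  A write-then-read
#' round trip reproduces all samples to 1e-9.
#'
#' @param path CSV file path.
#' @return [read_gait_csv()]: a `gait_cycle`.
#' @export
read_gait_csv <- function(path) {
  cols <- c("time_s", "flex_deg", "abd_deg", "rot_deg",
            "jrf_x_N", "jrf_y_N", "jrf_z_N")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("gait CSV is missing column(s): ", paste(missing, collapse = ", "))
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num))
      stop("malformed values in column ", cl, " at line(s): ",
           paste(bad + 1L, collapse = ", "))  # +1 for the header line
    }
    if (anyNA(v))
      stop("missing values in column ", cl, " at line(s): ",
           paste(which(is.na(v)) + 1L, collapse = ", "))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop("time_s must be strictly increasing; first violation at row ",
         which(dt <= 0)[1] + 1L)
  duration <- df$time_s[nrow(df)] - df$time_s[1]
  new_gait_cycle((df$time_s - df$time_s[1]) / duration,
                 df$flex_deg, df$abd_deg, df$rot_deg,
                 as.matrix(df[, c("jrf_x_N", "jrf_y_N", "jrf_z_N")]),
                 duration)
}

#' @rdname read_gait_csv
#' @param cycle a `gait_cycle`.
#' @export
write_gait_csv <- function(cycle, path) {
  stopifnot(inherits(cycle, "gait_cycle"))
  df <- data.frame(time_s = cycle$time * cycle$cycle_duration,
                   flex_deg = cycle$flexion_extension,
                   abd_deg = cycle$abduction_adduction,
                   rot_deg = cycle$internal_external_rotation,
                   jrf_x_N = cycle$jrf[, 1], jrf_y_N = cycle$jrf[, 2],
                   jrf_z_N = cycle$jrf[, 3])
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf(
    "<gait_cycle> %d samples, %.2f s, flexion [%.1f, %.1f] deg, peak |JRF| %.0f N\n",
    x$n_samples, x$cycle_duration, min(x$flexion_extension),
    max(x$flexion_extension), max(sqrt(rowSums(x$jrf^2)))))
  invisible(x)
}
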