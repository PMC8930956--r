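#' Default study configuration
#'
#' Bundles everything a full run needs: cohort and gait parameters, the
#' construct subset, mesh resolution, cycle count for extrapolation
#' (default exactly 1e6), and the seeds for every stochastic stage.
#'
#' @param seed master seed; cohort, patient-level and per-cycle seeds are
#'   derived from it deterministically.
#' @param configs subset of [IMPLANT_CONFIGS] to simulate.
#' @param n_patients cohort size.
#' @param n_steps time steps per gait cycle.
#' @param mesh_edge target mesh edge length (mm).
#' @param n_cycles extrapolation cycle count (default 1e6).
#' @param n_gait_cycles walking cycles averaged per patient (default 11).
#' @param gait_params [default_gait_params()] list.
#' @param implant_overrides passed to [make_implant_spec()].
#' @param ci_method Cohen's d CI method for the comparison table.
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 42L, configs = IMPLANT_CONFIGS,
                         n_patients = 15L, n_steps = 100L, mesh_edge = 0.75,
                         n_cycles = 1e6, n_gait_cycles = 11L,
                         gait_params = default_gait_params(),
                         implant_overrides = list(),
                         ci_method = "normal") {
  stopifnot(all(configs %in% IMPLANT_CONFIGS), n_patients >= 1, n_steps >= 15)
  structure(list(seed = as.integer(seed), configs = configs,
                 n_patients = as.integer(n_patients),
                 n_steps = as.integer(n_steps), mesh_edge = mesh_edge,
                 n_cycles = n_cycles, n_gait_cycles = as.integer(n_gait_cycles),
                 gait_params = gait_params,
                 implant_overrides = implant_overrides,
                 ci_method = ci_method),
            class = "study_config")
}

# averaged level-walking cycle for one patient, with patient-level
# amplitude variability and per-cycle jitter, all seeded from the config
patient_gait <- function(patient, i_patient, cfg) {
  gp <- cfg$gait_params
  amp_sd <- gp$gait$variability$patient_amp_sd
  amp_mult <- with_seed(cfg$seed + 1000L + i_patient,
                        max(1 - 2 * amp_sd, min(1 + 2 * amp_sd,
                                                stats::rnorm(1, 1, amp_sd))))
  gp$patient_amp_mult <- amp_mult
  cycles <- lapply(seq_len(cfg$n_gait_cycles), function(k)
    synthesize_gait(patient, gp, n_samples = cfg$n_steps + 1L,
                    seed = cfg$seed + 100L * i_patient + k))
  average_cycles(cycles)
}

#' Run the full wear study
#'
#' Generates the cohort, synthesizes and averages the per-patient walking
#' cycles, simulates one cycle of wear per patient and construct,
#' extrapolates to the configured cycle count, and reduces to the cohort
#' statistics: paired comparisons of every non-control construct against
#' the DM22PE control (volumetric and linear wear) and regressions of
#' dual-mobility volumetric wear on peak JRF and on BMI.  Deterministic
#' under a fixed config.
#'
#' @param config a [study_config()].
#' @param progress print one line per patient (default FALSE).
#' @return list of class `study_result`: `cohort`, `wear` (patient x
#'   construct table), `comparisons`, `regressions`, `config`, plus the
#'   extrapolated `fields` of the first patient (for wear-map export).
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- sample_cohort(config$n_patients,
                          n_male = min(config$gait_params$demographics$n_male,
                                       config$n_patients),
                          demographics = config$gait_params$demographics,
                          seed = config$seed)
  specs <- lapply(config$configs, make_implant_spec,
                  overrides = config$implant_overrides)
  names(specs) <- config$configs
  # meshes are geometry-only: build once per construct and reuse
  mesh_cache <- lapply(specs, function(sp) {
    radii <- articulation_radii(sp)
    m <- list(small = build_bearing_mesh(radii$small, config$mesh_edge, "small"))
    if (sp$is_dual_mobility)
      m$large <- build_bearing_mesh(radii$large, config$mesh_edge, "large")
    m
  })

  rows <- list()
  peak_jrf <- numeric(config$n_patients)
  first_fields <- NULL
  for (i in seq_len(config$n_patients)) {
    patient <- cohort[i, ]
    gait <- patient_gait(patient, i, config)
    peak_jrf[i] <- max(sqrt(rowSums(gait$jrf^2)))
    for (cid in config$configs) {
      cw <- simulate_cycle(specs[[cid]], patient, gait,
                           sim_params = list(mesh_edge = config$mesh_edge,
                                             meshes = mesh_cache[[cid]]))
      cw <- extrapolate_wear(cw, config$n_cycles)
      if (is.null(first_fields) && cid == config$configs[[1]])
        first_fields <- cw
      rows[[length(rows) + 1L]] <- wear_summary(cw)
    }
    if (progress)
      message(sprintf("patient %s (%d/%d) done", patient$id, i,
                      config$n_patients))
  }
  wear <- do.call(rbind, rows)
  cohort$peak_jrf <- peak_jrf

  comparisons <- NULL
  if ("DM22PE" %in% config$configs && length(config$configs) > 1) {
    ctrl <- wear[wear$config_id == "DM22PE", ]
    ctrl <- ctrl[order(ctrl$patient_id), ]
    others <- setdiff(config$configs, "DM22PE")
    cmp_rows <- list()
    for (cid in others) {
      grp <- wear[wear$config_id == cid, ]
      grp <- grp[order(grp$patient_id), ]
      for (measure in c("volumetric_wear", "linear_wear")) {
        row <- paired_comparison(ctrl[[measure]], grp[[measure]],
                                 label_a = "DM22PE", label_b = cid,
                                 ci_method = config$ci_method)
        row$measure <- measure
        cmp_rows[[length(cmp_rows) + 1L]] <- row
      }
    }
    comparisons <- do.call(rbind, cmp_rows)
  }

  regressions <- NULL
  dm_cfgs <- intersect(config$configs, c("DM22PE", "DM22XL"))
  if (length(dm_cfgs) && config$n_patients >= 3) {
    reg_rows <- list()
    for (cid in dm_cfgs) {
      v <- wear[wear$config_id == cid, ]
      v <- v[order(v$patient_id), ]$volumetric_wear
      co <- cohort[order(cohort$id), ]
      reg_rows[[length(reg_rows) + 1L]] <-
        regress_r2(co$peak_jrf, v, label = paste0(cid, "_vs_peak_jrf"))
      reg_rows[[length(reg_rows) + 1L]] <-
        regress_r2(co$bmi, v, label = paste0(cid, "_vs_bmi"))
    }
    regressions <- do.call(rbind, reg_rows)
  }

  structure(list(cohort = cohort, wear = wear, comparisons = comparisons,
                 regressions = regressions, config = config,
                 fields = first_fields),
            class = "study_result")
}

#' Mesh-convergence report for volumetric wear
#'
#' Runs the single-cycle wear simulation of a construct at a decreasing
#' sequence of mesh edge lengths and tabulates per-cycle volumetric wear
#' and its relative change from the next coarser level; flags the coarsest
#' level whose change is below `tol`.
#'
#' @param spec an `implant_spec`.
#' @param edge_lengths strictly decreasing vector of edge lengths (mm, >= 2
#'   levels).
#' @param reference_gait a `gait_cycle`.
#' @param patient cohort row matching the gait (provenance only).
#' @param tol relative-change tolerance (default 0.015).
#' @return data.frame: `edge_length`, `volumetric_wear` (per cycle, mm3),
#'   `rel_change`, `converged`.
#' @export
mesh_convergence_report <- function(spec, edge_lengths, reference_gait,
                                    patient = list(id = "ref"), tol = 0.015) {
  if (length(edge_lengths) < 2) stop("need at least two refinement levels")
  if (any(diff(edge_lengths) > 0))
    stop("edge_lengths must be non-increasing (coarse to fine)")
  v <- vapply(edge_lengths, function(e) {
    cw <- simulate_cycle(spec, patient, reference_gait,
                         sim_params = list(mesh_edge = e))
    s <- wear_summary(cw)
    s$volumetric_wear
  }, numeric(1))
  rel <- c(NA, abs(diff(v)) / abs(v[-1]))
  data.frame(edge_length = edge_lengths, volumetric_wear = v,
             rel_change = rel,
             converged = !is.na(rel) & rel < tol)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d patients x %d constructs, %.0f cycles\n",
              x$config$n_patients, length(x$config$configs),
              x$config$n_cycles))
  agg <- stats::aggregate(cbind(volumetric_wear, linear_wear) ~ config_id,
                          data = x$wear, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
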