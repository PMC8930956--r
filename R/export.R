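#' Export a wear-depth map on its bearing mesh
#'
#' Writes the mesh and the per-node wear scalar as legacy ASCII VTK
#' PolyData (readable by ParaView and similar viewers) or ASCII PLY with a
#' per-vertex `wear` property.  Full precision is kept so scalars
#' round-trip to 1e-9.
#'
#' @param wear_field a `wear_field`.
#' @param path output file path.
#' @param format `"vtk"` (default) or `"ply"`.
#' @return `path`, invisibly.
#' @export
export_wear_map <- function(wear_field, path, format = c("vtk", "ply")) {
  stopifnot(inherits(wear_field, "wear_field"))
  format <- match.arg(format)
  mesh <- wear_field$mesh
  xyz <- mesh$node_directions * mesh$radius
  tri <- mesh$triangles - 1L  # zero-based
  num <- function(x) sprintf("%.17g", x)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  if (format == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("dmwear wear map (%s articulation, %g cycles)",
                         wear_field$articulation_tag,
                         wear_field$cycles_represented),
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", nrow(xyz))), con)
    writeLines(paste(num(xyz[, 1]), num(xyz[, 2]), num(xyz[, 3])), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(tri), 4L * nrow(tri)), con)
    writeLines(paste(3L, tri[, 1], tri[, 2], tri[, 3]), con)
    writeLines(c(sprintf("POINT_DATA %d", nrow(xyz)),
                 "SCALARS wear_depth_mm double 1", "LOOKUP_TABLE default"), con)
    writeLines(num(wear_field$h), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(xyz)),
                 "property double x", "property double y", "property double z",
                 "property double wear",
                 sprintf("element face %d", nrow(tri)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(paste(num(xyz[, 1]), num(xyz[, 2]), num(xyz[, 3]),
                     num(wear_field$h)), con)
    writeLines(paste(3L, tri[, 1], tri[, 2], tri[, 3]), con)
  }
  invisible(path)
}

#' Read back a VTK wear map written by [export_wear_map()]
#'
#' Minimal reader for the legacy ASCII PolyData layout this package emits;
#' used for round-trip verification.
#'
#' @param path VTK file path.
#' @return list: `points` (n x 3), `triangles` (m x 3, one-based), `wear`
#'   (length n).
#' @export
read_wear_map_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n_pts <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  pts <- matrix(scan(text = lines[(ip + 1):(ip + n_pts)], quiet = TRUE),
                n_pts, 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1]
  n_tri <- as.integer(strsplit(lines[it], " +")[[1]][2])
  tri_raw <- matrix(scan(text = lines[(it + 1):(it + n_tri)], quiet = TRUE),
                    n_tri, 4, byrow = TRUE)
  is_ <- grep("^LOOKUP_TABLE", lines)[1]
  wear <- scan(text = lines[(is_ + 1):(is_ + n_pts)], quiet = TRUE)
  list(points = pts, triangles = tri_raw[, 2:4, drop = FALSE] + 1L,
       wear = wear)
}

# deterministic CSV writer: fixed float formatting, stable ordering
write_table_stable <- function(df, path) {
  fmt <- df
  for (cl in names(fmt))
    if (is.numeric(fmt[[cl]])) fmt[[cl]] <- sprintf("%.12g", fmt[[cl]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the study result tables
#'
#' Writes `wear_summaries.csv` (per patient x construct), `comparisons.csv`
#' (paired comparisons vs the DM22PE control, Table-1 shaped),
#' `regressions.csv`, and `metadata.json` (seed, sizes, construct list, a
#' config digest).  Formatting is fixed and ordering stable, so re-export
#' of the same result is byte-identical.
#'
#' @param result a `study_result` from [run_study()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
export_tables <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  missing <- c(if (is.null(result$wear) || !nrow(result$wear)) "wear table",
               if (is.null(result$cohort) || !nrow(result$cohort)) "cohort")
  if (length(missing))
    stop("result is incomplete; missing: ", paste(missing, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wear <- result$wear[order(result$wear$config_id, result$wear$patient_id), ]
  p <- file.path(dir, "wear_summaries.csv")
  write_table_stable(wear, p); paths <- c(paths, p)
  if (!is.null(result$comparisons)) {
    p <- file.path(dir, "comparisons.csv")
    write_table_stable(result$comparisons, p); paths <- c(paths, p)
  }
  if (!is.null(result$regressions)) {
    p <- file.path(dir, "regressions.csv")
    write_table_stable(result$regressions, p); paths <- c(paths, p)
  }
  cfg <- result$config
  meta <- list(seed = cfg$seed, n_patients = cfg$n_patients,
               configs = cfg$configs, n_steps = cfg$n_steps,
               mesh_edge = cfg$mesh_edge, n_cycles = cfg$n_cycles,
               n_gait_cycles = cfg$n_gait_cycles,
               config_digest = config_digest(cfg),
               package_version = as.character(utils::packageVersion("dmwear")))
  p <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

# small stable digest of the config (sum of a serialized representation)
config_digest <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %%
            .Machine$integer.max)
}
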