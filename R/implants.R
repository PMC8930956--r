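#' The five implant construct identifiers
#' @export
IMPLANT_CONFIGS <- c("DM22PE", "SD22PE", "SD32PE", "SD32XL", "DM22XL")

implant_presets_path <- function() {
  system.file("extdata", "implants.yaml", package = "dmwear", mustWork = TRUE)
}

#' Build an implant construct specification
#'
#' Returns the geometry and material definition of one of the five study
#' constructs: `DM22PE`/`DM22XL` (dual-mobility cup, 22.2-mm head, UHMWPE or
#' XLPE mobile liner) and `SD22PE`/`SD32PE`/`SD32XL` (conventional cups with
#' a fixed insert, 22.2- or 32-mm head).  All share a 52-mm external shell
#' and the 40 deg inclination / 15 deg anteversion cup placement.
#'
#' Liner wall thicknesses and radial clearances are not published for this
#' implant family; defaults are typical values for the implant class, stored
#' in the package preset file and overridable via `overrides` or a user
#' preset file.
#'
#' @param config_id one of `"DM22PE"`, `"SD22PE"`, `"SD32PE"`, `"SD32XL"`,
#'   `"DM22XL"`.
#' @param overrides named list replacing entries of the preset `defaults`
#'   block (e.g. `list(small_articulation_radial_clearance = 0.1)`).
#' @param presets_file optional path to a YAML preset file with the same
#'   schema as the packaged one.
#' @return list of class `implant_spec`.
#' @examples
#' spec <- make_implant_spec("DM22XL")
#' spec$head_diameter       # 22.2
#' spec$liner_material$name # "XLPE"
#' @export
make_implant_spec <- function(config_id, overrides = list(),
                              presets_file = NULL) {
  cfg <- yaml::read_yaml(if (is.null(presets_file)) implant_presets_path()
                         else presets_file)
  if (!is.character(config_id) || length(config_id) != 1 ||
      !config_id %in% names(cfg$constructs)) {
    stop("unknown config_id '", paste(config_id, collapse = ","),
         "'; valid constructs: ",
         paste(names(cfg$constructs), collapse = ", "))
  }
  con <- cfg$constructs[[config_id]]
  con_geo <- con[setdiff(names(con),
                         c("head_diameter", "liner_material", "is_dual_mobility"))]
  d <- utils::modifyList(utils::modifyList(cfg$defaults, con_geo), overrides)
  shell_id <- d$shell_external_diameter - 2 * d$shell_wall_thickness
  dm <- isTRUE(con$is_dual_mobility)
  liner_od <- if (dm) d$dm_liner_outer_diameter else shell_id
  spec <- list(
    config_id = config_id,
    head_diameter = con$head_diameter,
    shell_external_diameter = d$shell_external_diameter,
    liner_material = material_model(con$liner_material),
    is_dual_mobility = dm,
    small_articulation_radial_clearance = d$small_articulation_radial_clearance,
    large_articulation_radial_clearance =
      if (dm) d$large_articulation_radial_clearance else NA_real_,
    liner_outer_diameter = liner_od,
    liner_thickness_small = (liner_od - con$head_diameter) / 2,
    cup_inclination = d$cup_inclination,
    cup_anteversion = d$cup_anteversion
  )
  stopifnot(spec$head_diameter < spec$liner_outer_diameter,
            spec$liner_outer_diameter <= spec$shell_external_diameter,
            spec$small_articulation_radial_clearance > 0,
            spec$liner_thickness_small > 0)
  if (dm) stopifnot(spec$large_articulation_radial_clearance > 0)
  class(spec) <- "implant_spec"
  spec
}

#' @export
print.implant_spec <- function(x, ...) {
  cat(sprintf("<implant_spec %s> head %.1f mm, %s liner, %s, shell %.0f mm\n",
              x$config_id, x$head_diameter, x$liner_material$name,
              if (x$is_dual_mobility) "dual-mobility" else "conventional",
              x$shell_external_diameter))
  invisible(x)
}

#' Articulation radii of a construct
#'
#' Small articulation: femoral head against the concave liner bore
#' (radius = head radius).  Large articulation (dual-mobility only): convex
#' liner outer surface against the shell bore (radius = liner OD / 2).
#'
#' @param spec an `implant_spec`.
#' @return named list `small`, `large` (mm; `large` is `NA` for conventional
#'   cups).
#' @export
articulation_radii <- function(spec) {
  list(small = spec$head_diameter / 2,
       large = if (spec$is_dual_mobility) spec$liner_outer_diameter / 2
               else NA_real_)
}
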