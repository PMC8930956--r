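#' Bearing material models
#'
#' Elasto-plastic polyethylene parameters and the rigid cobalt-chromium
#' counterface used throughout the pipeline.  Conventional UHMWPE: elastic
#' modulus 500 MPa, Poisson ratio 0.45, yield stress 16 MPa, Archard wear
#' coefficient 10.656e-7 mm3/(N m).  Annealed highly cross-linked
#' polyethylene (XLPE): 1000 MPa, 0.45, 20 MPa, and exactly 20% of the
#' UHMWPE wear coefficient.  All metal-polyethylene interfaces share the
#' same friction coefficient mu = 0.01.
#'
#' @param name one of `"UHMWPE"`, `"XLPE"`, `"CoCr-rigid"`.
#' @return list of class `material_model` with fields `name`,
#'   `elastic_modulus` (MPa), `poisson_ratio`, `yield_stress` (MPa),
#'   `wear_coefficient` (mm3 N-1 m-1), `friction_coefficient`, `rigid`.
#' @examples
#' material_model("XLPE")$wear_coefficient /
#'   material_model("UHMWPE")$wear_coefficient  # exactly 0.2
#' @export
material_model <- function(name = c("UHMWPE", "XLPE", "CoCr-rigid")) {
  name <- match.arg(name)
  k_uhmwpe <- 10.656e-7
  m <- switch(name,
    "UHMWPE" = list(name = "UHMWPE", elastic_modulus = 500,
                    poisson_ratio = 0.45, yield_stress = 16,
                    wear_coefficient = k_uhmwpe,
                    friction_coefficient = 0.01, rigid = FALSE),
    "XLPE" = list(name = "XLPE", elastic_modulus = 1000,
                  poisson_ratio = 0.45, yield_stress = 20,
                  wear_coefficient = 0.2 * k_uhmwpe,
                  friction_coefficient = 0.01, rigid = FALSE),
    "CoCr-rigid" = list(name = "CoCr-rigid", elastic_modulus = NA_real_,
                        poisson_ratio = NA_real_, yield_stress = NA_real_,
                        wear_coefficient = NA_real_,
                        friction_coefficient = 0.01, rigid = TRUE)
  )
  class(m) <- "material_model"
  m
}
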