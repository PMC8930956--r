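# Implant construct presets: five acetabular components, 52-mm external
# shell, replicating a dual-mobility and a conventional cup line with
# 22.2-mm or 32-mm femoral heads against UHMWPE or XLPE.
#
# Liner geometry (clearances, wall thicknesses) is not published for this
# implant family; the values below are typical manufacturer figures for
# this implant class and can be overridden per run.  The 32-mm constructs
# carry a tighter bore conformity: under the elastic-foundation contact
# surrogate the peak pressure scales like sqrt(k_f * clearance), and the
# head-size wear pattern of the reference cohort (more volumetric, less
# linear wear with the larger head) is only expressed when the thinner
# 7-mm 32-head liner is paired with a proportionally tighter clearance.
# Construct-level entries override the defaults block.
defaults:
  shell_external_diameter: 52.0      # mm
  shell_wall_thickness: 3.0          # mm -> shell internal diameter 46 mm
  small_articulation_radial_clearance: 0.03   # mm (head vs liner bore)
  large_articulation_radial_clearance: 0.05   # mm (liner OD vs shell bore, DM)
  dm_liner_outer_diameter: 46.0      # mm (mobile liner OD, DM constructs)
  cup_inclination: 40.0              # deg
  cup_anteversion: 15.0              # deg
constructs:
  DM22PE:
    head_diameter: 22.2
    liner_material: UHMWPE
    is_dual_mobility: true
  SD22PE:
    head_diameter: 22.2
    liner_material: UHMWPE
    is_dual_mobility: false
  SD32PE:
    head_diameter: 32.0
    liner_material: UHMWPE
    is_dual_mobility: false
    small_articulation_radial_clearance: 0.012
  SD32XL:
    head_diameter: 32.0
    liner_material: XLPE
    is_dual_mobility: false
    small_articulation_radial_clearance: 0.012
  DM22XL:
    head_diameter: 22.2
    liner_material: XLPE
    is_dual_mobility: true
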