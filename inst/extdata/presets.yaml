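# Scenario presets for the synthetic-eye cohort generator.
# Every value here is a default and can be overridden from generate_cohort().
#
# Shared physics defaults (applied unless a preset overrides them):
#   viscosity_pa_s: 2.0e-3   effective vitreous viscosity
#   mesh_size_nm: 550        hindrance mesh size (bovine literature estimate)
#   bolus_sigma_mm: 1.0      initial Gaussian bolus width
#   bolus_mass: 1.0          arbitrary mass units
#   cells_across: 128        grid resolution across the eye diameter
defaults:
  viscosity_pa_s: 2.0e-3
  mesh_size_nm: 550
  bolus_sigma_mm: 1.0
  bolus_mass: 1.0
  cells_across: 128
  needle_depth_frac: 0.25
  background_level: 12
  noise_sigma: 2
  auto_target: 200

presets:
  ex_vivo_5dye:
    model: ex_vivo_pig
    dyes: ["3 kDa", "40 kDa", "70 kDa", "500 kDa", "2 MDa"]
    times_h: [24, 48]
    temperature_k: 277.15          # cold incubation
    injection_offset_mm: 4.0
    randomize_side: true
    eye_diameter_range_mm: [19.93514, 25.62603]
  in_vivo_2dye:
    model: in_vivo_pig
    dyes: ["40 kDa", "2 MDa"]
    times_h: [48]
    temperature_k: 310.15          # physiological
    injection_offset_mm: 3.5       # smaller miniature-pig eye
    randomize_side: false
    side: temporal
    eye_diameter_range_mm: [17.0, 20.0]
  plasmin:
    model: ex_vivo_pig_plasmin
    dyes: ["40 kDa", "2 MDa"]
    times_h: [24]
    temperature_k: 277.15
    injection_offset_mm: 4.0
    randomize_side: false
    side: temporal
    eye_diameter_range_mm: [19.93514, 25.62603]
    mesh_multiplier: 3             # enzymatic vitreolysis enlarges the mesh
  human_bursa:
    model: ex_vivo_human
    dyes: ["40 kDa", "2 MDa"]
    times_h: [24]
    temperature_k: 277.15
    injection_offset_mm: 4.0
    randomize_side: false
    side: temporal
    eye_diameter_range_mm: [22.0, 25.0]
    bursa:                         # liquefied no-flux pocket
      center_frac: [0.0, 0.4]      # (x, y) as fraction of eye radius
      radius_mm: 2.2
      n_vertices: 24
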