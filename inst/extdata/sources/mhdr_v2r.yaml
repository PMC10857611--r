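# microSelectron mHDR-v2r (revised) source design, transcribed from the
# published engineering drawing (all lengths in mm; converted to cm at load
# time).  The active core is 0.1 mm shorter and 0.05 mm narrower than in the
# mHDR-v2 design, and the capsule cavity is unchanged, leaving a dry-air gap
# around the core.  The gap is transcribed as BOTH annular (cavity diameter
# 0.65 mm vs core 0.60 mm) and distal (cavity 0.05 mm longer at each end than
# the core).
model: mHDR-v2r
units: mm
core_length: 3.5
core_diameter: 0.6
core_edge_radius: 0.1
capsule_outer_diameter: 0.9
capsule_tip_radius: 0.45
tip_to_core: 0.2           # cavity distal face -> outer capsule apex
capsule_total_length: 4.5
cavity_length: 3.6
cavity_diameter: 0.65
air_gap: true
cable_length: 2.0
cable_diameter: 0.7
materials:
  core: iridium
  gap: dry_air
  capsule: steel_capsule
  cable: steel_cable
phantom_radius_cm: 20
active_length_cm: 0.35
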