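# microSelectron mHDR-v2 source design, transcribed from the published
# engineering drawing (all lengths in mm; converted to cm at load time).
model: mHDR-v2
units: mm
core_length: 3.6           # active iridium cylinder
core_diameter: 0.65
core_edge_radius: 0.1      # rounding of the core edges (fillet, sphere-cylinder union)
capsule_outer_diameter: 0.9
capsule_tip_radius: 0.45   # spherical end cap of the capsule (transcription choice)
tip_to_core: 0.2           # core distal face -> outer capsule apex, along the axis
capsule_total_length: 4.5  # apex -> proximal capsule end where the cable attaches
cavity_length: 3.6         # capsule cavity equals the core: no air gap in this design
cavity_diameter: 0.65
air_gap: false
cable_length: 2.0          # modelled length of the drive cable
cable_diameter: 0.7
materials:
  core: iridium
  gap: dry_air
  capsule: steel_capsule
  cable: steel_cable
phantom_radius_cm: 20      # 40 cm diameter water sphere
active_length_cm: 0.36     # L used in the line-source geometry function
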