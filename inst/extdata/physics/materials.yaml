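# Material registry: element weight fractions and mass densities (g/cm3).
# The iridium metal density is an assumption (not stated alongside the source
# designs) and may be overridden when building a source model.
water:
  density: 0.998
  composition: {H: 0.111898, O: 0.888102}
dry_air:
  density: 0.00120
  composition: {"N": 0.755, "O": 0.232, "Ar": 0.013}
steel_capsule:
  density: 8.02
  composition: {Mn: 0.02, Si: 0.01, Cr: 0.17, Ni: 0.12, Fe: 0.68}
steel_cable:
  density: 4.81
  composition: {Mn: 0.02, Si: 0.01, Cr: 0.17, Ni: 0.12, Fe: 0.68}
iridium:
  density: 22.42
  density_assumed: true
  composition: {Ir: 1.0}
vacuum:
  density: 0.0
  composition: {}
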