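material,x0_g_cm2
water,36.328
dry_air,36.855
steel_capsule,14.229
steel_cable,14.229
iridium,6.5741
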