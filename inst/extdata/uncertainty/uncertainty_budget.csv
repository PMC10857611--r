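# Uncertainty budget (k = 1, percent) for the three headline quantities.
# type A = stochastic, B = systematic; "manufacturing" marks components that
# arise in source manufacture and are excluded from MC-to-MC comparisons;
# dynamic source design is a stated maximum rather than a standard error.
component,type,quantity,percent,manufacturing,is_bound
source geometry,B,D(0.10cm),0.46,TRUE,FALSE
capsule geometry,B,D(0.10cm),0.01,TRUE,FALSE
dynamic source design,B,D(0.10cm),4,TRUE,TRUE
192Ir photon spectrum,B,D(0.10cm),1,FALSE,FALSE
192Ir electron spectrum,B,D(0.10cm),0.03,FALSE,FALSE
MC physics,B,D(0.10cm),0.05,FALSE,FALSE
tally volume averaging,B,D(0.10cm),0.03,FALSE,FALSE
tally statistics,A,D(0.10cm),0.14,FALSE,FALSE
source geometry,B,D(1.0cm),0.46,TRUE,FALSE
capsule geometry,B,D(1.0cm),0.01,TRUE,FALSE
dynamic source design,B,D(1.0cm),0.4,TRUE,TRUE
192Ir photon spectrum,B,D(1.0cm),1,FALSE,FALSE
192Ir electron spectrum,B,D(1.0cm),0.03,FALSE,FALSE
MC physics,B,D(1.0cm),0.05,FALSE,FALSE
tally statistics,A,D(1.0cm),0.19,FALSE,FALSE
source geometry,B,K(10cm),0.46,TRUE,FALSE
capsule geometry,B,K(10cm),0.01,TRUE,FALSE
dynamic source design,B,K(10cm),0.04,TRUE,TRUE
192Ir photon spectrum,B,K(10cm),1,FALSE,FALSE
192Ir electron spectrum,B,K(10cm),0.03,FALSE,FALSE
MC physics,B,K(10cm),0.05,FALSE,FALSE
tally statistics,A,K(10cm),0.30,FALSE,FALSE
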