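# 192Ir internal conversion electron lines, >=10 keV and <=669 keV
# relative transcription rescaled by 2.3169 to 0.1531 electrons/Bq
energy_keV,intensity_per_Bq
110.02,0.000926755
122.52,0.00106577
127.44,0.00301196
131.92,0.00695067
193.31,0.00150598
217.56,0.0268759
230.06,0.0303512
238.11,0.0421674
282.08,0.00426308
292.70,0.00101943
294.58,0.0049118
302.63,0.00688116
305.16,0.00115844
313.21,0.00162182
389.67,0.00973093
406.18,0.00159865
454.19,0.00162182
464.77,0.000393871
510.19,0.00166816
526.02,0.00278027
534.07,0.00180717
590.53,0.000486547
598.58,0.000301196
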