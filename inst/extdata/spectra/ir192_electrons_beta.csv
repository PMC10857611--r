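# 192Ir beta- continuum, allowed-shape Fermi spectra of the branches
# 10 keV bins on [10, 669] keV; intensities per decay per bin;
# rescaled by 0.998678 to integrate to 0.9192 electrons/Bq
e_lo_keV,e_hi_keV,intensity_per_Bq
10.0,20.0,0.0307041
20.0,30.0,0.0304989
30.0,40.0,0.0302587
40.0,50.0,0.029986
50.0,60.0,0.0296836
60.0,70.0,0.0293541
70.0,80.0,0.0290001
80.0,90.0,0.0286228
90.0,100.0,0.0282154
100.0,110.0,0.0277759
110.0,120.0,0.0273062
120.0,130.0,0.0268081
130.0,140.0,0.0262837
140.0,150.0,0.0257353
150.0,160.0,0.0251652
160.0,170.0,0.024576
170.0,180.0,0.0239705
180.0,190.0,0.0233515
190.0,200.0,0.0227221
200.0,210.0,0.0220854
210.0,220.0,0.021445
220.0,230.0,0.0208042
230.0,240.0,0.0201667
240.0,250.0,0.0195363
250.0,260.0,0.0189171
260.0,270.0,0.0183046
270.0,280.0,0.0176789
280.0,290.0,0.0170379
290.0,300.0,0.0163832
300.0,310.0,0.0157165
310.0,320.0,0.0150397
320.0,330.0,0.0143546
330.0,340.0,0.0136632
340.0,350.0,0.0129674
350.0,360.0,0.0122694
360.0,370.0,0.0115713
370.0,380.0,0.0108753
380.0,390.0,0.0101838
390.0,400.0,0.00949904
400.0,410.0,0.00882355
410.0,420.0,0.00815981
420.0,430.0,0.00751041
430.0,440.0,0.00687799
440.0,450.0,0.00626527
450.0,460.0,0.00567505
460.0,470.0,0.00511019
470.0,480.0,0.00457361
480.0,490.0,0.00406831
490.0,500.0,0.00359738
500.0,510.0,0.00316395
510.0,520.0,0.00277123
520.0,530.0,0.00242249
530.0,540.0,0.00212109
540.0,550.0,0.00186065
550.0,560.0,0.00161621
560.0,570.0,0.00138426
570.0,580.0,0.00116595
580.0,590.0,0.000962444
590.0,600.0,0.000774925
600.0,610.0,0.00060461
610.0,620.0,0.000452738
620.0,630.0,0.00032057
630.0,640.0,0.000209394
640.0,650.0,0.000120518
650.0,660.0,5.5277e-05
660.0,669.0,1.4597e-05
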