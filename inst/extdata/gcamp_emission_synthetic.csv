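wavelength_nm,value
480,0.050
485,0.110
490,0.220
495,0.350
500,0.500
505,0.820
510,1.000
515,0.970
520,0.930
525,0.800
530,0.680
535,0.580
540,0.490
545,0.410
550,0.350
555,0.300
560,0.260
565,0.220
570,0.180
575,0.155
580,0.130
585,0.110
590,0.090
595,0.077
600,0.065
605,0.057
610,0.050
615,0.042
620,0.035
625,0.031
630,0.027
635,0.023
640,0.020
645,0.017
650,0.015
655,0.013
660,0.011
665,0.010
670,0.008
675,0.007
680,0.006
685,0.005
690,0.005
695,0.004
700,0.004
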