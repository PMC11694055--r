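threshold,benign_10pct,malignant_98pct,benign_2pct,malignant_99pct
0,176770,180211,178262,176263
100,1809,35059,2605,21288
200,470,12925,1222,11870
300,235,4208,588,6573
400,91,1132,283,3414
500,27,211,126,1745
600,2,19,6,728
700,0,4,0,254
800,0,0,0,132
900,0,0,0,51
1000,0,0,0,0
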