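locus,phi
TPOX,0.0775
TH01,0.0973
CSF1PO,0.1171
D5S818,0.1369
D7S820,0.1568
D13S317,0.1766
D16S539,0.1964
D3S1358,0.2162
vWA,0.2360
D8S1179,0.2558
D19S433,0.2756
D2S441,0.2954
D10S1248,0.3153
D1S1656,0.3351
D12S391,0.3549
D21S11,0.3747
D2S1338,0.3945
FGA,0.4143
D18S51,0.4341
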