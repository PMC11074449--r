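locus,offset_bp,motif_bp,dye
D3S1358,50,4,blue
vWA,110,4,blue
D16S539,210,4,blue
CSF1PO,250,4,blue
TPOX,290,4,blue
D8S1179,88,4,green
D21S11,100,4,green
D18S51,240,4,green
D2S441,50,4,yellow
D19S433,70,4,yellow
TH01,150,4,yellow
FGA,170,4,yellow
D22S1045,63,3,red
D5S818,110,4,red
D13S317,190,4,red
D7S820,235,4,red
SE33,330,4,red
D10S1248,55,4,purple
D1S1656,130,4,purple
D12S391,150,4,purple
D2S1338,250,4,purple
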