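garden_id,plantation,habitat,Ni,Gt,Go,AliveY6
G01,W,HT,42,13,31,20
G02,W,HT,44,16,28,15
G03,W,HT,43,11,26,15
G04,W,SF,42,12,17,3
G05,W,SF,42,9,18,11
G06,W,SF,44,11,20,7
G07,E,SF,42,22,34,22
G08,E,SF,41,19,23,15
G09,E,SF,42,19,31,26
G10,E,HT,42,22,31,23
G11,E,HT,43,18,29,16
G12,E,HT,43,12,24,17
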