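mother_id,provenance,ecotype,habitat_of_mother,Ni,Gt,Go,AliveY6
W426,E,glo,SF,36,27,31,18
W503,E,glo,SF,37,21,29,12
M837,E,sp1,HT,36,25,30,14
W424,E,sp1,HT,38,38,38,17
W425,E,sp1,HT,39,31,37,15
W463,W,glo,SF,36,16,18,9
W466,W,glo,SF,36,2,13,12
W497,W,glo,SF,36,7,23,17
W498,W,glo,SF,35,1,10,10
W465,W,sp1,HT,36,0,8,7
W474,W,sp1,HT,36,0,18,14
W475,W,sp1,HT,36,4,20,16
W476,W,sp1,HT,36,0,16,15
W477,W,sp1,HT,37,12,21,14
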