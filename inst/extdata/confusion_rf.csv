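predicted,AGRI,BARE,CLSH,DBLF,ENLF,GRAS,OPSH,URBN,WATR
AGRI,548,5,10,0,0,19,9,2,0
BARE,0,52,3,0,0,0,8,0,1
CLSH,5,3,248,6,0,11,22,7,0
DBLF,0,0,10,184,1,0,0,0,0
ENLF,0,0,1,0,55,0,0,0,0
GRAS,26,3,17,0,0,159,4,4,1
OPSH,0,9,9,0,0,0,35,0,0
URBN,4,2,1,0,0,0,2,151,4
WATR,1,0,0,0,0,0,0,0,38
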