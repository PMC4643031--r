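predicted,AGRI,BARE,CLSH,DBLF,ENLF,GRAS,OPSH,URBN,WATR
AGRI,558,2,8,0,0,11,8,4,0
BARE,1,49,2,0,0,0,11,0,0
CLSH,5,3,262,8,0,10,19,5,2
DBLF,0,0,7,182,0,0,0,0,0
ENLF,0,0,1,0,56,0,0,0,0
GRAS,14,2,11,0,0,164,2,2,1
OPSH,0,12,6,0,0,0,37,0,0
URBN,3,1,0,0,0,0,0,152,1
WATR,1,0,0,0,0,0,0,0,38
UNCE,2,5,2,0,0,4,3,1,2
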