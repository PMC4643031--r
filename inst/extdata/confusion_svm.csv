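predicted,AGRI,BARE,CLSH,DBLF,ENLF,GRAS,OPSH,URBN,WATR
AGRI,555,4,8,0,0,15,6,6,0
BARE,2,48,1,0,0,0,10,0,1
CLSH,3,5,264,11,0,7,17,3,1
DBLF,0,0,6,178,0,0,0,0,0
ENLF,0,0,1,0,55,0,0,0,0
GRAS,18,4,11,1,0,166,6,2,1
OPSH,1,11,6,0,0,1,40,0,0
URBN,4,1,1,0,0,0,1,153,0
WATR,1,1,1,0,1,0,0,0,41
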