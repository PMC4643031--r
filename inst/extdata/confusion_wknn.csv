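predicted,AGRI,BARE,CLSH,DBLF,ENLF,GRAS,OPSH,URBN,WATR
AGRI,547,3,5,0,0,11,7,5,0
BARE,2,50,3,0,0,0,10,0,0
CLSH,12,6,263,11,0,16,16,7,4
DBLF,0,0,7,179,0,1,0,0,0
ENLF,0,0,0,0,56,0,0,0,0
GRAS,19,1,11,0,0,161,4,3,1
OPSH,1,12,9,0,0,0,43,0,0
URBN,2,2,1,0,0,0,0,149,3
WATR,1,0,0,0,0,0,0,0,36
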