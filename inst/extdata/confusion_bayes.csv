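predicted,AGRI,BARE,CLSH,DBLF,ENLF,GRAS,OPSH,URBN,WATR
AGRI,556,3,5,0,0,9,7,6,0
BARE,1,53,3,0,0,0,11,0,0
CLSH,3,2,265,8,0,11,20,3,2
DBLF,0,0,7,182,0,0,0,0,0
ENLF,0,0,0,0,56,0,0,0,0
GRAS,17,3,9,0,0,169,5,2,1
OPSH,1,11,9,0,0,0,37,0,0
URBN,5,2,1,0,0,0,0,153,1
WATR,1,0,0,0,0,0,0,0,40
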