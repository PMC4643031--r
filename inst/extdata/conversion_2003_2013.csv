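from,AGRI,BARE,CLSH,DBLF,ENLF,GRAS,OPSH
AGRI,236821,6421,43901,2583,592,60392,4870
BARE,2225,4670,4810,0,0,1824,2219
CLSH,8930,303,73201,12497,997,16079,2289
DBLF,336,0.1,5985,50959,535,1098,0.8
ENLF,14,0,314,736,1897,10,0.2
GRAS,34385,479,29696,5219,281,56823,1469
OPSH,2674,1671,10794,2,11,3218,6296
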