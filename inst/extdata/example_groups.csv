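species,group,retained
bg_001,background,TRUE
bg_002,background,TRUE
bg_003,background,TRUE
bg_004,background,TRUE
bg_005,background,TRUE
bg_006,background,TRUE
bg_007,background,TRUE
bg_008,background,TRUE
bg_009,background,TRUE
bg_010,background,TRUE
bg_011,background,TRUE
bg_012,background,TRUE
cA_001,cladeA,TRUE
cA_002,cladeA,TRUE
cA_003,cladeA,TRUE
cA_004,cladeA,TRUE
cA_005,cladeA,TRUE
cA_006,cladeA,TRUE
cB_001,cladeB,TRUE
cB_002,cladeB,TRUE
cB_003,cladeB,TRUE
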