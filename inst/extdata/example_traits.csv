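species,specimen,trait,value
bg_001,1,scapula_EL,1.393696700801239
bg_002,1,scapula_EL,2.32300876914756
bg_003,1,scapula_EL,2.241683544238517
bg_004,1,scapula_EL,2.1757242127230922
bg_005,1,scapula_EL,2.1742847660470375
bg_006,1,scapula_EL,2.2315413659689893
bg_007,1,scapula_EL,2.51868102589544
bg_008,1,scapula_EL,2.1783939005121304
bg_009,1,scapula_EL,2.650060735789826
bg_010,1,scapula_EL,1.5664202900549633
bg_011,1,scapula_EL,1.3861802328585666
bg_012,1,scapula_EL,2.615925508943342
cA_001,1,scapula_EL,2.1933559058209595
cA_002,1,scapula_EL,2.516757349781084
cA_003,1,scapula_EL,2.496725971455709
cA_004,1,scapula_EL,2.2018807458133614
cA_005,1,scapula_EL,2.3489663422870666
cA_006,1,scapula_EL,2.3866058183377543
cB_001,1,scapula_EL,2.280488955448117
cB_002,1,scapula_EL,2.074985657894778
cB_003,1,scapula_EL,2.281802393601445
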