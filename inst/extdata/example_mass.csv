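species,ln_mass
bg_001,4.589320262704331
bg_002,6.462545449700218
bg_003,6.709205148788675
bg_004,6.517124684908434
bg_005,6.262941548685227
bg_006,6.730515572021654
bg_007,7.003654713249928
bg_008,5.925513814968317
bg_009,7.540048453952259
bg_010,4.726559595940985
bg_011,4.604048560622677
bg_012,8.328501276426097
cA_001,8.009737143083571
cA_002,8.485229460282447
cA_003,8.434127865322411
cA_004,8.010639405274244
cA_005,8.42178352145837
cA_006,8.425978684862818
cB_001,8.436834490520145
cB_002,7.8282916168656245
cB_003,8.571045334756977
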