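(((bg_004:42.94176574,(bg_008:29.35305194,bg_012:29.35305194):13.5887138):8.532087341,((bg_007:12.61426528,bg_003:12.61426528):18.68573472,(cB_002:21.91,(cB_003:14.88804757,cB_001:14.88804757):7.021952427):9.39):20.17385308):18.52614692,(((bg_006:24.5,((cA_001:16.67826486,(cA_003:9.242557176,cA_004:9.242557176):7.435707687):0.4717351367,((cA_006:4.74862748,cA_005:4.74862748):10.11381803,cA_002:14.86244551):2.287554486):7.35):34.83322631,(bg_009:20.0259328,((bg_011:1.583955849,bg_001:1.583955849):7.008104323,bg_010:8.592060172):11.43387263):39.30729351):4.727031502,(bg_005:15.67578087,bg_002:15.67578087):48.38447695):5.939742185);
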