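species,bodyweight_g,clearance,clearance_unit,mature
synthetic_sp01,1,2707000,nL/h,TRUE
synthetic_sp02,3.594,10510000,nL/h,TRUE
synthetic_sp03,12.92,26900000,nL/h,TRUE
synthetic_sp04,46.42,123800000,nL/h,TRUE
synthetic_sp05,166.8,153800000,nL/h,TRUE
synthetic_sp06,599.5,702400000,nL/h,TRUE
synthetic_sp07,2154,1.811e+09,nL/h,TRUE
synthetic_sp08,7743,2.219e+09,nL/h,TRUE
synthetic_sp09,27830,6.569e+09,nL/h,TRUE
synthetic_sp10,1e+05,2.946e+10,nL/h,TRUE
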