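label,g1,g2,g3,absA1,absA2,absA3,sA1,sA2,sA3,shf_values,shf_assignment,g_strain,A_strain,lw_gauss,lw_lorentz,freq_GHz,isotope
apo_14N_X,2.027,2.095,2.261,255,110,336,+,+,-,43;43;28,His;His;NH2,0;0.02;0.007,130;55;160,0.6,0.6,9.3046,14N
apo_15N_X,2.029,2.081,2.261,255,115,336,+,+,-,60;60;40,His;His;NH2,0;0.025;0.005,160;60;160,0.6,0.6,9.2973,15N
apo_15N_Q,2.032,2.112,2.260,255,115,340,+,+,-,60;60;40,His;His;NH2,0;0.045;0.007,20;10;120,4.5,4.5,35.00,15N
chitin_14N_X,2.042,2.053,2.205,80,85,620,?,-,-,40;40;32,His;His;NH2,0.004;0;0.007,20;20;20,0.4,0.4,9.2988,14N
chitin_15N_X,2.038,2.046,2.209,88,95,610,?,-,-,56;56;45,His;His;NH2,0.005;0;0.009,10;10;10,0.5,0.6,9.2884,15N
chitin_15N_Q,2.046,2.057,2.208,80,90,610,?,-,-,55;55;45,His;His;NH2,0.005;0;0.003,90;40;240,1.3,1.3,35.05,15N
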