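condition,label,orientation,aiso,aiso_err,T,T_err,e1,e2,e3
apo,N(A),perp,2.40,0.02,0.34,0.03,10,100,60
apo,N(B),perp,2.00,0.05,0.30,0.05,0,94,20
apo,N(A),par,2.40,0.02,0.34,0.05,10,100,60
apo,N(B),par,2.00,0.05,0.30,0.05,0,94,20
chitin,N(A),perp,2.20,0.05,0.40,0.02,10,110,60
chitin,N(B),perp,1.90,0.05,0.35,0.05,120,70,0
chitin,N(A),par,2.25,0.05,0.40,0.05,10,110,60
chitin,N(B),par,1.85,0.05,0.35,0.05,120,60,0
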