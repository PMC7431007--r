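condition,label,aiso,T,e1,e2,e3,K,K_err,eta,eta_err,q1,q2,q3
apo,N(A),1.6,0.3,10,100,60,1.75,0.05,0.7,0.05,60,10,95
apo,N(B),1.3,0.25,0,94,20,1.40,0.05,0.85,0.05,20,0,-95
chitin,N(A),1.55,0.35,10,110,60,1.35,0.05,0.9,0.05,60,30,95
chitin,N(B),1.25,0.30,120,70,0,1.40,0.05,0.8,0.05,10,-10,-80
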