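id,smiles,s_pharma_to_ref,docking_score,interactions
A,CCOc1ccccc1,0.80,-10.0,Cys133;Lys82
B,O=Cc1ccc(O)cc1,0.90,-10.0,Cys133;Lys82
C,Cc1ccc2ccccc2c1,0.95,-10.0,Cys133;Lys82
D,CCc1ccc(O)cc1,0.92,-8.5,Cys133;Lys82
E,CCc1ccc(N)cc1,0.93,-9.5,Lys82;Asp194
F,CCc1ccc(OC)cc1,0.91,-9.5,Cys133
G,CCc1ccc(O)cc1N,0.95,-9.5,Cys133;Lys82
H,CCCc1ccccc1O,0.96,-10.2,Cys133;Glu140
I,CCc1ccncc1O,0.94,-9.2,Cys133;Asp194;Glu140
J,CCOCCN(C)CCO,0.90,-9.8,Cys133;Lys82
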