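# Pinned medicinal-chemistry structural-alert patterns, version 1.
# Curated set of common reactive/unstable motifs applied at the
# drug-likeness stage of the screening triage.
# Format: <name><TAB><SMARTS>
acyl_halide	[CX3](=O)[F,Cl,Br,I]
aldehyde	[CX3H1](=O)[#6]
peroxide	[OX2][OX2]
azo	[#6]N=N[#6]
isocyanate	N=C=O
isothiocyanate	N=C=S
thiocyanate	SC#N
alkyl_halide_activated	[CX4;!$(C(F)(F)F)][Br,I]
michael_acceptor	[CX3]=[CX3][CX3](=O)[!N]
nitro	[N+](=O)[O-]
nitroso	[NX2]=O
hydrazine	[NX3][NX3]
epoxide	C1OC1
aziridine	C1NC1
disulfide	[SX2][SX2]
anhydride	[CX3](=O)O[CX3](=O)
imine_of_aldehyde	[CX3H1]=[NX2]
quaternary_carbon_halide	[CX4]([Cl,Br,I])([Cl,Br,I])
phosphorus_halide	P[F,Cl,Br,I]
sulfonyl_halide	S(=O)(=O)[F,Cl,Br,I]
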