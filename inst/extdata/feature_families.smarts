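# Pinned pharmacophore feature definitions, version 1 (do not edit in place;
# results are frozen against this file).
# Format: <family-name><TAB><SMARTS>, one pattern per line; '#' comments.
# Eight families in fixed id order (0-7): acceptor, donor, aromatic,
# pos_ionizable, neg_ionizable, hydrophobe, lumped_hydrophobe, zn_binder.
# A feature's member atoms are the atoms matched by the pattern.
#
# 0: hydrogen-bond acceptor
acceptor	[OX2H1;!$(OS(=O)=O)]
acceptor	[OX2H0;!$(O=*);!$(OC=[O,S,N])]
acceptor	[OX1;$(O=[C,S,P,N])]
acceptor	[O-;!$([O-][N+])]
acceptor	[NX3;H0,H1,H2;+0;!$(N=*);!$(N-a);!$(NC=[O,S,N]);!$(NS(=O)=O)]
acceptor	[nX2;H0;+0]
acceptor	[NX2;$(N=C);+0]
acceptor	[NX1;$(N#C)]
# 1: hydrogen-bond donor
donor	[OX2H1]
donor	[SX2H1]
donor	[N;!a;H1,H2,H3;+0,+1]
donor	[nH1]
donor	[NX2;H1;+0]
# 2: aromatic ring
aromatic	a1aaaa1
aromatic	a1aaaaa1
aromatic	a1aaaaaa1
# 3: positively ionizable
pos_ionizable	[+;!$([+]~[-]);!$([N+](=O)[O-])]
pos_ionizable	[NX3;H2,H1;+0;!$(N-a);!$(NC=[O,S,N]);!$(NS(=O)=O);!$(NC#N);!$(N[O,N])]
pos_ionizable	NC(=N)N
pos_ionizable	[NX2;$(N=C(N)N)]
# 4: negatively ionizable
neg_ionizable	C(=O)[OX1H0-,OX2H1]
neg_ionizable	S(=O)(=O)[OX1H0-,OX2H1]
neg_ionizable	P(=O)[OX1H0-,OX2H1]
neg_ionizable	c1nnn[nH]1
# 5: hydrophobe (acyclic carbon chains; terminal carbon in an all-carbon
#    neighbourhood, and halogens on carbon)
hydrophobe	[CX4;!R;D1;$(C-[C;!$(C~[!#6;!#1])])]
hydrophobe	[Cl,Br,I;X1;$([*]-[#6])]
# 6: lumped hydrophobe (whole hydrophobic rings, one feature per ring)
lumped_hydrophobe	[C;R]1[C;R][C;R]1
lumped_hydrophobe	[C;R]1[C;R][C;R][C;R]1
lumped_hydrophobe	[C;R]1[C;R][C;R][C;R][C;R]1
lumped_hydrophobe	[C;R]1[C;R][C;R][C;R][C;R][C;R]1
lumped_hydrophobe	[C;R]1[C;R][C;R][C;R][C;R][C;R][C;R]1
lumped_hydrophobe	c1ccccc1
# 7: zinc binder
zn_binder	[SX2H1]
zn_binder	C(=O)N[OX2H1]
zn_binder	S(=O)(=O)[NX3;H1,H2]
zn_binder	[CX3](=O)[CX3](=O)
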