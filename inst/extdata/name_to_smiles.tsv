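water	O
methanol	CO
ethanol	CCO
isopropanol	CC(C)O
acetone	CC(C)=O
acetonitrile	CC#N
ethyl acetate	CCOC(C)=O
tetrahydrofuran	C1CCOC1
dichloromethane	ClCCl
chloroform	ClC(Cl)Cl
toluene	Cc1ccccc1
benzene	c1ccccc1
hexane	CCCCCC
heptane	CCCCCCC
diethyl ether	CCOCC
1,4-dioxane	C1COCCO1
N,N-dimethylformamide	CN(C)C=O
dimethyl sulfoxide	CS(C)=O
acetic acid	CC(O)=O
trifluoroacetic acid	OC(=O)C(F)(F)F
hydrochloric acid	Cl
sulfuric acid	OS(=O)(=O)O
sodium hydroxide	[OH-].[Na+]
ammonium chloride	[NH4+].[Cl-]
potassium carbonate	[K+].[K+].[O-]C([O-])=O
cesium carbonate	[Cs+].[Cs+].[O-]C([O-])=O
sodium borohydride	[Na+].[BH4-]
sodium hydride	[Na+].[H-]
triethylamine	CCN(CC)CC
N,N-diisopropylethylamine	CCN(C(C)C)C(C)C
benzaldehyde	O=Cc1ccccc1
acetophenone	CC(=O)c1ccccc1
aniline	Nc1ccccc1
benzylamine	NCc1ccccc1
benzyl chloride	ClCc1ccccc1
benzyl alcohol	OCc1ccccc1
4-bromoaniline	Nc1ccc(Br)cc1
4-nitrobenzaldehyde	O=Cc1ccc(cc1)[N+]([O-])=O
2-aminophenol	Nc1ccccc1O
3-chlorobenzoic acid	OC(=O)c1cccc(Cl)c1
phenylboronic acid	OB(O)c1ccccc1
imidazole	c1cnc[nH]1
morpholine	C1COCCN1
piperidine	C1CCNCC1
pyrrolidine	C1CCNC1
piperazine	C1CNCCN1
iodomethane	CI
thionyl chloride	ClS(Cl)=O
oxalyl chloride	ClC(=O)C(Cl)=O
triphenylphosphine	c1ccc(cc1)P(c1ccccc1)c1ccccc1
sodium sulfate	[Na+].[Na+].[O-]S([O-])(=O)=O
magnesium sulfate	[Mg+2].[O-]S([O-])(=O)=O
brine	O.[Na+].[Cl-]
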