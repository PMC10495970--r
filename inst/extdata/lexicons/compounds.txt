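3-cyano-4-((1-methylethyl)oxy)benzoic acid
1-benzyl-2-(chloromethyl)pyrrolidine
4-bromoaniline
4-nitrobenzaldehyde
2-aminophenol
3-chlorobenzoic acid
ethyl 4-aminobenzoate
methyl 2-bromoacetate
benzyl chloride
benzaldehyde
acetophenone
4-methoxybenzylamine
2,4-dichlorophenol
N,N-diisopropylethylamine
triethylamine
EDC
HOBt
HATU
DMAP
sodium borohydride
lithium aluminium hydride
sodium hydride
potassium carbonate
cesium carbonate
sodium hydroxide
hydrochloric acid
sulfuric acid
acetic acid
trifluoroacetic acid
ammonium chloride
saturated aqueous NH4Cl
saturated aqueous NaHCO3
brine
2-bromopyridine
3-aminopyridine
4-(dimethylamino)pyridine
2-chloroquinoline
6-bromoindole
1H-pyrazole-4-carboxylic acid
5-methylisoxazole-3-carboxylic acid
2-thiophenecarboxaldehyde
furan-2-carboxylic acid
cyclohexanone
cyclopropylamine
tert-butyl carbazate
di-tert-butyl dicarbonate
benzyl alcohol
phenylboronic acid
4-fluorophenylboronic acid
palladium acetate
tetrakis(triphenylphosphine)palladium(0)
copper(I) iodide
zinc chloride
N-bromosuccinimide
N-chlorosuccinimide
m-chloroperoxybenzoic acid
oxalyl chloride
thionyl chloride
methanesulfonyl chloride
p-toluenesulfonyl chloride
4-toluenesulfonic acid
hydrazine hydrate
hydroxylamine hydrochloride
O-(7-azabenzotriazol-1-yl)-N,N,N,N-tetramethyluronium hexafluorophosphate
2-(trimethylsilyl)ethoxymethyl chloride
tert-butyldimethylsilyl chloride
imidazole
morpholine
piperidine
pyrrolidine
piperazine
N-methylpiperazine
aniline
benzylamine
diethylamine
dimethylamine hydrochloride
2-methoxyethylamine
allyl bromide
propargyl bromide
iodomethane
ethyl iodide
dimethyl sulfate
ethyl chloroformate
methyl chloroformate
2-bromo-1-(4-fluorophenyl)ethanone
1-(4-chlorophenyl)piperazine
tert-butyl 4-oxopiperidine-1-carboxylate
4-oxo-4H-chromene-3-carbaldehyde
2-amino-4-methylthiazole
5-bromo-2-methoxypyridine
3,4-dimethoxybenzaldehyde
2,6-lutidine
4-methylmorpholine N-oxide
tetrabutylammonium fluoride
sodium azide
potassium cyanide
trimethylsilyl cyanide
diethyl azodicarboxylate
triphenylphosphine
9-borabicyclo[3.3.1]nonane
diisobutylaluminium hydride
n-butyllithium
lithium diisopropylamide
sodium methoxide
potassium tert-butoxide
2-(4-bromophenyl)acetic acid
methyl 3-oxobutanoate
ethyl acetoacetate
diethyl malonate
malononitrile
urea
thiourea
guanidine hydrochloride
glycine ethyl ester hydrochloride
L-proline
4-piperidone hydrochloride
2-chloro-5-nitropyrimidine
4,6-dichloropyrimidine
2-bromo-5-iodopyridine
3-(trifluoromethyl)phenylhydrazine
4-hydrazinobenzoic acid
phenyl isocyanate
cyclohexyl isocyanate
benzoyl chloride
4-nitrobenzoyl chloride
acetic anhydride
trifluoroacetic anhydride
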