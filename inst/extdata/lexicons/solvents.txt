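water
ethyl acetate
tetrahydrofuran
dichloromethane
chloroform
methanol
ethanol
isopropanol
acetonitrile
acetone
toluene
benzene
hexane
heptane
petroleum ether
diethyl ether
1,4-dioxane
N,N-dimethylformamide
dimethyl sulfoxide
N-methyl-2-pyrrolidone
1,2-dichloroethane
tert-butyl methyl ether
2-methyltetrahydrofuran
xylene
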