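name,difference
hydrogenation/dehydrogenation,H2
oxidation/hydroxylation,O
hydration/dehydration,H2O
methylation/demethylation,CH2
ethylation,C2H4
desaturation pair (C2H2),C2H2
hydroxymethylation,CH2O
formylation,CO
carboxylation/decarboxylation,CO2
acetylation,C2H2O
glycolylation,C2H2O2
propionylation,C3H4O
malonylation,C3H2O3
amination (NH),NH
amination (NH3),NH3
HCN addition,CHN
thiolation,S
phosphorylation,HPO3
sulfation,SO3
glycosylation (hexose),C6H10O5
pentosylation,C5H8O4
glucuronidation,C6H8O6
taurine conjugation,C2H5NO2S
glycine residue,C2H3NO
alanine residue,C3H5NO
serine residue,C3H5NO2
proline residue,C5H7NO
valine residue,C5H9NO
threonine residue,C4H7NO2
cysteine residue,C3H5NOS
leucine/isoleucine residue,C6H11NO
asparagine residue,C4H6N2O2
aspartate residue,C4H5NO3
glutamine residue,C5H8N2O2
lysine residue,C6H12N2O
glutamate residue,C5H7NO3
methionine residue,C5H9NOS
histidine residue,C6H7N3O
phenylalanine residue,C9H9NO
arginine residue,C6H12N4O
tyrosine residue,C9H9NO2
tryptophan residue,C11H10N2O
adenine transfer,C5H5N5
phosphoethanolamine,C2H6NO3P
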