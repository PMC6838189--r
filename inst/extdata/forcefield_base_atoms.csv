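# psihelix nonbonded base-atom parameter table, version 1
# charge in e; sigma in Angstrom; epsilon in kcal/mol
# PSU charges are a documented surrogate derived from U (see ?default_forcefield)
residue_code,atom_name,charge,sigma,epsilon
A,N9,-0.0251,3.25,0.17
A,C8,0.2006,3.3997,0.086
A,H8,0.1553,2.4215,0.015
A,N7,-0.6073,3.25,0.17
A,C5,0.0515,3.3997,0.086
A,C6,0.7009,3.3997,0.086
A,N6,-0.9019,3.25,0.17
A,H61,0.4115,1.0691,0.0157
A,H62,0.4115,1.0691,0.0157
A,N1,-0.7615,3.25,0.17
A,C2,0.5875,3.3997,0.086
A,H2,0.0473,2.4215,0.015
A,N3,-0.6997,3.25,0.17
A,C4,0.3053,3.3997,0.086
G,N9,0.0492,3.25,0.17
G,C8,0.1374,3.3997,0.086
G,H8,0.164,2.4215,0.015
G,N7,-0.5709,3.25,0.17
G,C5,0.1744,3.3997,0.086
G,C6,0.477,3.3997,0.086
G,O6,-0.5597,2.9599,0.21
G,N1,-0.4787,3.25,0.17
G,H1,0.3424,1.0691,0.0157
G,C2,0.7657,3.3997,0.086
G,N2,-0.9672,3.25,0.17
G,H21,0.4364,1.0691,0.0157
G,H22,0.4364,1.0691,0.0157
G,N3,-0.6323,3.25,0.17
G,C4,0.1222,3.3997,0.086
C,N1,-0.0484,3.25,0.17
C,C6,0.0053,3.3997,0.086
C,H6,0.1958,2.5106,0.015
C,C5,-0.5215,3.3997,0.086
C,H5,0.1928,2.5996,0.015
C,C4,0.8185,3.3997,0.086
C,N4,-0.953,3.25,0.17
C,H41,0.4234,1.0691,0.0157
C,H42,0.4234,1.0691,0.0157
C,N3,-0.7584,3.25,0.17
C,C2,0.7538,3.3997,0.086
C,O2,-0.6252,2.9599,0.21
U,N1,0.0418,3.25,0.17
U,C6,-0.1126,3.3997,0.086
U,H6,0.2188,2.5106,0.015
U,C5,-0.3635,3.3997,0.086
U,H5,0.1811,2.5996,0.015
U,C4,0.5952,3.3997,0.086
U,O4,-0.5761,2.9599,0.21
U,N3,-0.3549,3.25,0.17
U,H3,0.3154,1.0691,0.0157
U,C2,0.4687,3.3997,0.086
U,O2,-0.5477,2.9599,0.21
PSU,N1,-0.3549,3.25,0.17
PSU,HN1,0.1725,1.0691,0.0157
PSU,C2,0.4687,3.3997,0.086
PSU,O2,-0.5477,2.9599,0.21
PSU,N3,-0.3549,3.25,0.17
PSU,H3,0.3154,1.0691,0.0157
PSU,C4,0.5952,3.3997,0.086
PSU,O4,-0.5761,2.9599,0.21
PSU,C5,0.0418,3.3997,0.086
PSU,C6,-0.1126,3.3997,0.086
PSU,H6,0.2188,2.5106,0.015
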