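resname,atom,element,x,y,z
ALA,N,N,-0.966,0.493,1.500
ALA,CA,C,0.257,0.418,0.692
ALA,C,C,-0.094,0.017,-0.716
ALA,O,O,-1.056,-0.682,-0.923
ALA,CB,C,1.204,-0.620,1.296
ARG,N,N,-0.469,1.110,-0.993
ARG,CA,C,0.004,2.294,-1.708
ARG,C,C,-0.907,2.521,-2.901
ARG,O,O,-1.827,1.789,-3.242
ARG,CB,C,1.475,2.150,-2.127
ARG,CG,C,1.745,1.017,-3.130
ARG,CD,C,3.210,0.954,-3.557
ARG,NE,N,4.071,0.726,-2.421
ARG,CZ,C,5.469,0.624,-2.528
ARG,NH1,N,6.259,0.404,-1.405
ARG,NH2,N,6.078,0.744,-3.773
ASN,N,N,-0.293,1.686,0.094
ASN,CA,C,-0.448,0.292,-0.340
ASN,C,C,-1.846,-0.179,-0.031
ASN,O,O,-2.510,0.402,0.794
ASN,CB,C,0.562,-0.588,0.401
ASN,CG,C,1.960,-0.197,-0.002
ASN,OD1,O,2.132,0.697,-0.804
ASN,ND2,N,3.019,-0.841,0.527
ASP,N,N,-0.317,1.688,0.066
ASP,CA,C,-0.470,0.286,-0.344
ASP,C,C,-1.868,-0.180,-0.029
ASP,O,O,-2.534,0.415,0.786
ASP,CB,C,0.539,-0.580,0.413
ASP,CG,C,1.938,-0.195,0.004
ASP,OD1,O,2.109,0.681,-0.810
ASP,OD2,O,2.992,-0.826,0.543
CYS,N,N,1.585,0.483,-0.081
CYS,CA,C,0.141,0.450,0.186
CYS,C,C,-0.095,0.006,1.606
CYS,O,O,0.685,-0.742,2.143
CYS,CB,C,-0.533,-0.530,-0.774
CYS,SG,S,-0.247,0.004,-2.484
GLN,N,N,1.858,-0.148,1.125
GLN,CA,C,0.517,0.451,1.112
GLN,C,C,-0.236,0.022,2.344
GLN,O,O,-0.005,-1.049,2.851
GLN,CB,C,-0.236,-0.013,-0.135
GLN,CG,C,0.529,0.421,-1.385
GLN,CD,C,-0.213,-0.036,-2.614
GLN,OE1,O,-1.252,-0.650,-2.500
GLN,NE2,N,0.277,0.236,-3.839
GLU,N,N,1.199,1.867,-0.117
GLU,CA,C,1.138,0.515,0.453
GLU,C,C,2.364,-0.260,0.041
GLU,O,O,3.010,0.096,-0.916
GLU,CB,C,-0.113,-0.200,-0.062
GLU,CG,C,-1.360,0.517,0.461
GLU,CD,C,-2.593,-0.187,-0.046
GLU,OE1,O,-2.485,-1.161,-0.753
GLU,OE2,O,-3.811,0.269,0.287
GLY,N,N,1.931,0.090,-0.034
GLY,CA,C,0.761,-0.799,-0.008
GLY,C,C,-0.498,0.029,-0.005
GLY,O,O,-0.429,1.235,-0.023
HIS,N,N,-0.040,-1.210,0.053
HIS,CA,C,1.172,-1.709,0.652
HIS,C,C,1.083,-3.207,0.905
HIS,O,O,0.040,-3.770,1.222
HIS,CB,C,1.484,-0.975,1.962
HIS,CG,C,2.940,-1.060,2.353
HIS,ND1,N,3.380,-2.075,3.129
HIS,CD2,C,3.960,-0.251,2.046
HIS,CE1,C,4.693,-1.908,3.317
HIS,NE2,N,5.058,-0.801,2.662
ILE,N,N,-1.944,0.335,-0.343
ILE,CA,C,-0.487,0.519,-0.369
ILE,C,C,0.066,-0.032,-1.657
ILE,O,O,-0.484,-0.958,-2.203
ILE,CB,C,0.140,-0.219,0.814
ILE,CG1,C,-0.421,0.341,2.122
ILE,CG2,C,1.658,-0.027,0.788
ILE,CD1,C,0.206,-0.397,3.305
LEU,N,N,-1.661,0.627,-0.406
LEU,CA,C,-0.205,0.441,-0.467
LEU,C,C,0.180,-0.055,-1.836
LEU,O,O,-0.591,-0.731,-2.474
LEU,CB,C,0.221,-0.583,0.585
LEU,CG,C,-0.170,-0.079,1.976
LEU,CD1,C,0.256,-1.104,3.029
LEU,CD2,C,0.526,1.254,2.250
LYS,N,N,1.422,1.796,0.198
LYS,CA,C,1.394,0.355,0.484
LYS,C,C,2.657,-0.284,-0.032
LYS,O,O,3.316,0.275,-0.876
LYS,CB,C,0.184,-0.278,-0.206
LYS,CG,C,-1.102,0.282,0.407
LYS,CD,C,-2.313,-0.351,-0.283
LYS,CE,C,-3.598,0.208,0.329
LYS,NZ,N,-4.761,-0.400,-0.332
MET,N,N,-1.816,0.142,-1.166
MET,CA,C,-0.392,0.499,-1.214
MET,C,C,0.206,0.002,-2.504
MET,O,O,-0.236,-0.989,-3.033
MET,CB,C,0.334,-0.145,-0.032
MET,CG,C,-0.273,0.359,1.277
MET,SD,S,0.589,-0.405,2.678
MET,CE,C,-0.314,0.353,4.056
PHE,N,N,1.317,0.962,1.014
PHE,CA,C,-0.020,0.426,1.300
PHE,C,C,-0.109,0.047,2.756
PHE,O,O,0.879,-0.317,3.346
PHE,CB,C,-0.270,-0.809,0.434
PHE,CG,C,-0.181,-0.430,-1.020
PHE,CD1,C,1.031,-0.498,-1.680
PHE,CD2,C,-1.314,-0.018,-1.698
PHE,CE1,C,1.112,-0.150,-3.015
PHE,CE2,C,-1.231,0.333,-3.032
PHE,CZ,C,-0.018,0.265,-3.691
PRO,N,N,-0.816,1.108,0.254
PRO,CA,C,0.001,-0.107,0.509
PRO,C,C,1.408,0.091,0.005
PRO,O,O,1.650,0.980,-0.777
PRO,CB,C,-0.703,-1.227,-0.286
PRO,CG,C,-2.163,-0.753,-0.439
PRO,CD,C,-2.218,0.614,0.276
SER,N,N,1.525,0.493,-0.608
SER,CA,C,0.100,0.469,-0.252
SER,C,C,-0.053,0.004,1.173
SER,O,O,0.751,-0.760,1.649
SER,CB,C,-0.642,-0.489,-1.184
SER,OG,O,-0.496,-0.049,-2.535
THR,N,N,1.543,-0.702,0.430
THR,CA,C,0.122,-0.706,0.056
THR,C,C,-0.038,-0.090,-1.309
THR,O,O,0.732,0.761,-1.683
THR,CB,C,-0.675,0.104,1.079
THR,OG1,O,-0.193,1.448,1.103
THR,CG2,C,-0.511,-0.521,2.466
TRP,N,N,1.278,1.121,2.059
TRP,CA,C,-0.008,0.417,1.970
TRP,C,C,-0.490,0.076,3.357
TRP,O,O,0.308,-0.130,4.240
TRP,CB,C,0.168,-0.868,1.161
TRP,CG,C,0.650,-0.526,-0.225
TRP,CD1,C,1.928,-0.418,-0.622
TRP,CD2,C,-0.186,-0.256,-1.396
TRP,NE1,N,1.978,-0.095,-1.951
TRP,CE2,C,0.701,0.014,-2.454
TRP,CE3,C,-1.564,-0.210,-1.615
TRP,CZ2,C,0.190,0.314,-3.712
TRP,CZ3,C,-2.044,0.086,-2.859
TRP,CH2,C,-1.173,0.348,-3.907
TYR,N,N,1.320,0.952,1.428
TYR,CA,C,-0.018,0.429,1.734
TYR,C,C,-0.103,0.094,3.201
TYR,O,O,0.886,-0.254,3.799
TYR,CB,C,-0.274,-0.831,0.907
TYR,CG,C,-0.189,-0.496,-0.559
TYR,CD1,C,1.022,-0.589,-1.219
TYR,CD2,C,-1.324,-0.102,-1.244
TYR,CE1,C,1.103,-0.282,-2.563
TYR,CE2,C,-1.247,0.210,-2.587
TYR,CZ,C,-0.032,0.118,-3.252
TYR,OH,O,0.044,0.420,-4.574
VAL,N,N,1.564,-0.642,0.454
VAL,CA,C,0.145,-0.698,0.079
VAL,C,C,-0.037,-0.093,-1.288
VAL,O,O,0.703,0.784,-1.664
VAL,CB,C,-0.682,0.086,1.098
VAL,CG1,C,-0.497,-0.528,2.487
VAL,CG2,C,-0.218,1.543,1.119
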