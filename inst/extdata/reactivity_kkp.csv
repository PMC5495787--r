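resname,kkp
CYS,52.3
TRP,20.0
TYR,20.0
MET,13.1
PHE,10.6
HIS,7.4
ARG,5.4
ILE,2.8
LEU,2.6
VAL,1.31
PRO,1.0
GLN,0.83
THR,0.78
LYS,0.54
SER,0.49
GLU,0.35
ASP,0.12
ALA,0.12
ASN,0.075
GLY,0.026
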