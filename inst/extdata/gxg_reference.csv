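resname,gxg_sasa_A2
ALA,65.79
ARG,205.93
ASN,114.83
ASP,107.31
CYS,97.76
GLN,143.96
GLU,137.13
GLY,0
HIS,154.36
ILE,140.77
LEU,138.09
LYS,167.56
MET,158.21
PHE,176.07
PRO,94.06
SER,77.17
THR,103.38
TRP,217.49
TYR,186.33
VAL,117.27
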