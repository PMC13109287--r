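resname,H
GLY,0.10
ALA,0.15
VAL,0.25
LEU,0.30
ILE,0.35
MET,0.45
PHE,0.50
TRP,0.55
TYR,0.60
CYS,1.00
SER,1.10
PRO,1.25
THR,1.35
ASN,1.55
GLN,1.65
HIS,2.40
LYS,2.90
ARG,3.10
ASP,3.20
GLU,3.32
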