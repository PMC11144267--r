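# United-atom Wildman-Crippen atomic logP contributions for protein heavy
# atoms (hydrogen contributions folded onto their bonded heavy atom).
# Context: mid-chain residue in a Gly-X-Gly tripeptide, neutral side chains.
# version: 1.0
residue,atom,element,f
ALA,N,N,-0.4954
ALA,CA,C,-0.0821
ALA,C,C,-0.2783
ALA,O,O,-0.1526
ALA,CB,C,0.5131
CYS,N,N,-0.4954
CYS,CA,C,-0.0821
CYS,C,C,-0.2783
CYS,O,O,-0.1526
CYS,CB,C,0.0425
CYS,SG,S,0.3805
ASP,N,N,-0.4954
ASP,CA,C,-0.0821
ASP,C,C,-0.2783
ASP,O,O,-0.1526
ASP,CB,C,0.3901
ASP,CG,C,-0.2783
ASP,OD1,O,-0.1526
ASP,OD2,O,0.0087
GLU,N,N,-0.4954
GLU,CA,C,-0.0821
GLU,C,C,-0.2783
GLU,O,O,-0.1526
GLU,CB,C,0.3901
GLU,CG,C,0.3901
GLU,CD,C,-0.2783
GLU,OE1,O,-0.1526
GLU,OE2,O,0.0087
PHE,N,N,-0.4954
PHE,CA,C,-0.0821
PHE,C,C,-0.2783
PHE,O,O,-0.1526
PHE,CB,C,0.1944
PHE,CG,C,0.136
PHE,CD1,C,0.2811
PHE,CD2,C,0.2811
PHE,CE1,C,0.2811
PHE,CE2,C,0.2811
PHE,CZ,C,0.2811
GLY,N,N,-0.4954
GLY,CA,C,0.0425
GLY,C,C,-0.2783
GLY,O,O,-0.1526
HIS,N,N,-0.4954
HIS,CA,C,-0.0821
HIS,C,C,-0.2783
HIS,O,O,-0.1526
HIS,CB,C,0.1944
HIS,CG,C,0.136
HIS,ND1,N,-0.3239
HIS,CD2,C,0.2811
HIS,CE1,C,0.2811
HIS,NE2,N,-0.1097
ILE,N,N,-0.4954
ILE,CA,C,-0.0821
ILE,C,C,-0.2783
ILE,O,O,-0.1526
ILE,CB,C,0.123
ILE,CG1,C,0.5131
ILE,CG2,C,0.3901
ILE,CD1,C,0.5131
LYS,N,N,-0.4954
LYS,CA,C,-0.0821
LYS,C,C,-0.2783
LYS,O,O,-0.1526
LYS,CB,C,0.3901
LYS,CG,C,0.3901
LYS,CD,C,0.3901
LYS,CE,C,0.0425
LYS,NZ,N,-0.5906
LEU,N,N,-0.4954
LEU,CA,C,-0.0821
LEU,C,C,-0.2783
LEU,O,O,-0.1526
LEU,CB,C,0.3901
LEU,CG,C,0.123
LEU,CD1,C,0.5131
LEU,CD2,C,0.5131
MET,N,N,-0.4954
MET,CA,C,-0.0821
MET,C,C,-0.2783
MET,O,O,-0.1526
MET,CB,C,0.3901
MET,CG,C,0.0425
MET,SD,S,0.6482
MET,CE,C,0.1655
ASN,N,N,-0.4954
ASN,CA,C,-0.0821
ASN,C,C,-0.2783
ASN,O,O,-0.1526
ASN,CB,C,0.3901
ASN,CG,C,-0.2783
ASN,OD1,O,-0.1526
ASN,ND2,N,-0.5906
PRO,N,N,-0.3187
PRO,CA,C,-0.0821
PRO,C,C,-0.2783
PRO,O,O,-0.1526
PRO,CB,C,0.3901
PRO,CG,C,0.3901
PRO,CD,C,0.0425
GLN,N,N,-0.4954
GLN,CA,C,-0.0821
GLN,C,C,-0.2783
GLN,O,O,-0.1526
GLN,CB,C,0.3901
GLN,CG,C,0.3901
GLN,CD,C,-0.2783
GLN,OE1,O,-0.1526
GLN,NE2,N,-0.5906
ARG,N,N,-0.4954
ARG,CA,C,-0.0821
ARG,C,C,-0.2783
ARG,O,O,-0.1526
ARG,CB,C,0.3901
ARG,CG,C,0.3901
ARG,CD,C,0.0425
ARG,NE,N,-0.4954
ARG,CZ,C,-0.2783
ARG,NH1,N,0.2981
ARG,NH2,N,-0.5906
SER,N,N,-0.4954
SER,CA,C,-0.0821
SER,C,C,-0.2783
SER,O,O,-0.1526
SER,CB,C,0.0425
SER,OG,O,-0.557
THR,N,N,-0.4954
THR,CA,C,-0.0821
THR,C,C,-0.2783
THR,O,O,-0.1526
THR,CB,C,-0.0821
THR,OG1,O,-0.557
THR,CG2,C,0.5131
VAL,N,N,-0.4954
VAL,CA,C,-0.0821
VAL,C,C,-0.2783
VAL,O,O,-0.1526
VAL,CB,C,0.123
VAL,CG1,C,0.5131
VAL,CG2,C,0.5131
TRP,N,N,-0.4954
TRP,CA,C,-0.0821
TRP,C,C,-0.2783
TRP,O,O,-0.1526
TRP,CB,C,0.1944
TRP,CG,C,0.136
TRP,CD1,C,0.2811
TRP,CD2,C,0.2955
TRP,NE1,N,-0.1097
TRP,CE2,C,0.2955
TRP,CE3,C,0.2811
TRP,CZ2,C,0.2811
TRP,CZ3,C,0.2811
TRP,CH2,C,0.2811
TYR,N,N,-0.4954
TYR,CA,C,-0.0821
TYR,C,C,-0.2783
TYR,O,O,-0.1526
TYR,CB,C,0.1944
TYR,CG,C,0.136
TYR,CD1,C,0.2811
TYR,CD2,C,0.2811
TYR,CE1,C,0.2811
TYR,CE2,C,0.2811
TYR,CZ,C,0.5437
TYR,OH,O,-0.557
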