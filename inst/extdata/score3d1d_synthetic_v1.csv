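# SYNTHETIC 3D-1D environment compatibility score table (surrogate).
# NOT the published VERIFY3D table: scores are constructed from united-atom
# Wildman-Crippen side-chain hydrophobicity, side-chain polar capacity and
# secondary-structure propensities. Higher = more favourable environment.
# Any analysis using this table carries score_table='synthetic-v1' metadata.
# version: synthetic-1.0
residue,env_class,secondary,score
ALA,B1,helix,0.3843
ARG,B1,helix,-0.1674
ASN,B1,helix,-0.2636
ASP,B1,helix,-0.115
CYS,B1,helix,0.4529
GLN,B1,helix,-0.1669
GLU,B1,helix,-0.0182
GLY,B1,helix,0.087
HIS,B1,helix,0.1369
ILE,B1,helix,0.6388
LEU,B1,helix,0.6388
LYS,B1,helix,0.0473
MET,B1,helix,0.6312
PHE,B1,helix,0.6876
PRO,B1,helix,-0.1389
SER,B1,helix,-0.1046
THR,B1,helix,0.0567
TRP,B1,helix,0.833
TYR,B1,helix,0.5106
VAL,B1,helix,0.5421
ALA,B1,sheet,0.3843
ARG,B1,sheet,-0.1674
ASN,B1,sheet,-0.2636
ASP,B1,sheet,-0.115
CYS,B1,sheet,0.4529
GLN,B1,sheet,-0.1669
GLU,B1,sheet,-0.0182
GLY,B1,sheet,0.187
HIS,B1,sheet,0.1369
ILE,B1,sheet,0.6388
LEU,B1,sheet,0.6388
LYS,B1,sheet,0.0473
MET,B1,sheet,0.6312
PHE,B1,sheet,0.6876
PRO,B1,sheet,0.0611
SER,B1,sheet,-0.1046
THR,B1,sheet,0.0567
TRP,B1,sheet,0.833
TYR,B1,sheet,0.5106
VAL,B1,sheet,0.5421
ALA,B1,other,0.3843
ARG,B1,other,-0.1674
ASN,B1,other,-0.2636
ASP,B1,other,-0.115
CYS,B1,other,0.4529
GLN,B1,other,-0.1669
GLU,B1,other,-0.0182
GLY,B1,other,0.387
HIS,B1,other,0.1369
ILE,B1,other,0.6388
LEU,B1,other,0.6388
LYS,B1,other,0.0473
MET,B1,other,0.6312
PHE,B1,other,0.6876
PRO,B1,other,0.4611
SER,B1,other,-0.1046
THR,B1,other,0.0567
TRP,B1,other,0.833
TYR,B1,other,0.5106
VAL,B1,other,0.5421
ALA,B2,helix,0.1958
ARG,B2,helix,0.0211
ASN,B2,helix,-0.0751
ASP,B2,helix,0.0735
CYS,B2,helix,0.3684
GLN,B2,helix,0.0216
GLU,B2,helix,0.1703
GLY,B2,helix,-0.1015
HIS,B2,helix,0.3254
ILE,B2,helix,0.4503
LEU,B2,helix,0.4503
LYS,B2,helix,0.2358
MET,B2,helix,0.4427
PHE,B2,helix,0.4991
PRO,B2,helix,-0.3274
SER,B2,helix,0.0839
THR,B2,helix,0.2452
TRP,B2,helix,0.8785
TYR,B2,helix,0.6991
VAL,B2,helix,0.3536
ALA,B2,sheet,0.1958
ARG,B2,sheet,0.0211
ASN,B2,sheet,-0.0751
ASP,B2,sheet,0.0735
CYS,B2,sheet,0.3684
GLN,B2,sheet,0.0216
GLU,B2,sheet,0.1703
GLY,B2,sheet,-0.0015
HIS,B2,sheet,0.3254
ILE,B2,sheet,0.4503
LEU,B2,sheet,0.4503
LYS,B2,sheet,0.2358
MET,B2,sheet,0.4427
PHE,B2,sheet,0.4991
PRO,B2,sheet,-0.1274
SER,B2,sheet,0.0839
THR,B2,sheet,0.2452
TRP,B2,sheet,0.8785
TYR,B2,sheet,0.6991
VAL,B2,sheet,0.3536
ALA,B2,other,0.1958
ARG,B2,other,0.0211
ASN,B2,other,-0.0751
ASP,B2,other,0.0735
CYS,B2,other,0.3684
GLN,B2,other,0.0216
GLU,B2,other,0.1703
GLY,B2,other,0.1985
HIS,B2,other,0.3254
ILE,B2,other,0.4503
LEU,B2,other,0.4503
LYS,B2,other,0.2358
MET,B2,other,0.4427
PHE,B2,other,0.4991
PRO,B2,other,0.2726
SER,B2,other,0.0839
THR,B2,other,0.2452
TRP,B2,other,0.8785
TYR,B2,other,0.6991
VAL,B2,other,0.3536
ALA,B3,helix,0.0398
ARG,B3,helix,0.1771
ASN,B3,helix,0.0809
ASP,B3,helix,0.2295
CYS,B3,helix,0.2124
GLN,B3,helix,0.1776
GLU,B3,helix,0.3263
GLY,B3,helix,-0.2575
HIS,B3,helix,0.4814
ILE,B3,helix,0.2943
LEU,B3,helix,0.2943
LYS,B3,helix,0.3918
MET,B3,helix,0.2867
PHE,B3,helix,0.3431
PRO,B3,helix,-0.4834
SER,B3,helix,0.2399
THR,B3,helix,0.3362
TRP,B3,helix,0.7225
TYR,B3,helix,0.6601
VAL,B3,helix,0.1976
ALA,B3,sheet,0.0398
ARG,B3,sheet,0.1771
ASN,B3,sheet,0.0809
ASP,B3,sheet,0.2295
CYS,B3,sheet,0.2124
GLN,B3,sheet,0.1776
GLU,B3,sheet,0.3263
GLY,B3,sheet,-0.1575
HIS,B3,sheet,0.4814
ILE,B3,sheet,0.2943
LEU,B3,sheet,0.2943
LYS,B3,sheet,0.3918
MET,B3,sheet,0.2867
PHE,B3,sheet,0.3431
PRO,B3,sheet,-0.2834
SER,B3,sheet,0.2399
THR,B3,sheet,0.3362
TRP,B3,sheet,0.7225
TYR,B3,sheet,0.6601
VAL,B3,sheet,0.1976
ALA,B3,other,0.0398
ARG,B3,other,0.1771
ASN,B3,other,0.0809
ASP,B3,other,0.2295
CYS,B3,other,0.2124
GLN,B3,other,0.1776
GLU,B3,other,0.3263
GLY,B3,other,0.0425
HIS,B3,other,0.4814
ILE,B3,other,0.2943
LEU,B3,other,0.2943
LYS,B3,other,0.3918
MET,B3,other,0.2867
PHE,B3,other,0.3431
PRO,B3,other,0.1166
SER,B3,other,0.2399
THR,B3,other,0.3362
TRP,B3,other,0.7225
TYR,B3,other,0.6601
VAL,B3,other,0.1976
ALA,P1,helix,0.23
ARG,P1,helix,-0.0566
ASN,P1,helix,-0.0903
ASP,P1,helix,-0.0383
CYS,P1,helix,0.4172
GLN,P1,helix,-0.0564
GLU,P1,helix,-0.0044
GLY,P1,helix,0.0155
HIS,P1,helix,0.1344
ILE,P1,helix,0.3191
LEU,P1,helix,0.3191
LYS,P1,helix,0.0185
MET,P1,helix,0.3587
PHE,P1,helix,0.3362
PRO,P1,helix,-0.3431
SER,P1,helix,0.0498
THR,P1,helix,0.1486
TRP,P1,helix,0.547
TYR,P1,helix,0.3497
VAL,P1,helix,0.2853
ALA,P1,sheet,0.23
ARG,P1,sheet,-0.0566
ASN,P1,sheet,-0.0903
ASP,P1,sheet,-0.0383
CYS,P1,sheet,0.4172
GLN,P1,sheet,-0.0564
GLU,P1,sheet,-0.0044
GLY,P1,sheet,0.1155
HIS,P1,sheet,0.1344
ILE,P1,sheet,0.3191
LEU,P1,sheet,0.3191
LYS,P1,sheet,0.0185
MET,P1,sheet,0.3587
PHE,P1,sheet,0.3362
PRO,P1,sheet,-0.1431
SER,P1,sheet,0.0498
THR,P1,sheet,0.1486
TRP,P1,sheet,0.547
TYR,P1,sheet,0.3497
VAL,P1,sheet,0.2853
ALA,P1,other,0.23
ARG,P1,other,-0.0566
ASN,P1,other,-0.0903
ASP,P1,other,-0.0383
CYS,P1,other,0.4172
GLN,P1,other,-0.0564
GLU,P1,other,-0.0044
GLY,P1,other,0.3155
HIS,P1,other,0.1344
ILE,P1,other,0.3191
LEU,P1,other,0.3191
LYS,P1,other,0.0185
MET,P1,other,0.3587
PHE,P1,other,0.3362
PRO,P1,other,0.2569
SER,P1,other,0.0498
THR,P1,other,0.1486
TRP,P1,other,0.547
TYR,P1,other,0.3497
VAL,P1,other,0.2853
ALA,P2,helix,-0.095
ARG,P2,helix,0.2684
ASN,P2,helix,0.2347
ASP,P2,helix,0.2867
CYS,P2,helix,0.0922
GLN,P2,helix,0.2686
GLU,P2,helix,0.3206
GLY,P2,helix,-0.3095
HIS,P2,helix,0.4204
ILE,P2,helix,-0.0059
LEU,P2,helix,-0.0059
LYS,P2,helix,0.3435
MET,P2,helix,0.0337
PHE,P2,helix,0.0112
PRO,P2,helix,-0.6681
SER,P2,helix,0.3358
THR,P2,helix,0.3046
TRP,P2,helix,0.313
TYR,P2,helix,0.3757
VAL,P2,helix,-0.0397
ALA,P2,sheet,-0.095
ARG,P2,sheet,0.2684
ASN,P2,sheet,0.2347
ASP,P2,sheet,0.2867
CYS,P2,sheet,0.0922
GLN,P2,sheet,0.2686
GLU,P2,sheet,0.3206
GLY,P2,sheet,-0.2095
HIS,P2,sheet,0.4204
ILE,P2,sheet,-0.0059
LEU,P2,sheet,-0.0059
LYS,P2,sheet,0.3435
MET,P2,sheet,0.0337
PHE,P2,sheet,0.0112
PRO,P2,sheet,-0.4681
SER,P2,sheet,0.3358
THR,P2,sheet,0.3046
TRP,P2,sheet,0.313
TYR,P2,sheet,0.3757
VAL,P2,sheet,-0.0397
ALA,P2,other,-0.095
ARG,P2,other,0.2684
ASN,P2,other,0.2347
ASP,P2,other,0.2867
CYS,P2,other,0.0922
GLN,P2,other,0.2686
GLU,P2,other,0.3206
GLY,P2,other,-0.0095
HIS,P2,other,0.4204
ILE,P2,other,-0.0059
LEU,P2,other,-0.0059
LYS,P2,other,0.3435
MET,P2,other,0.0337
PHE,P2,other,0.0112
PRO,P2,other,-0.0681
SER,P2,other,0.3358
THR,P2,other,0.3046
TRP,P2,other,0.313
TYR,P2,other,0.3757
VAL,P2,other,-0.0397
ALA,E,helix,-0.2798
ARG,E,helix,0.3629
ASN,E,helix,0.4591
ASP,E,helix,0.3105
CYS,E,helix,-0.0624
GLN,E,helix,0.3624
GLU,E,helix,0.2137
GLY,E,helix,-0.3225
HIS,E,helix,0.2536
ILE,E,helix,-0.5343
LEU,E,helix,-0.5343
LYS,E,helix,0.1482
MET,E,helix,-0.3967
PHE,E,helix,-0.5831
PRO,E,helix,-0.9566
SER,E,helix,0.4951
THR,E,helix,0.3338
TRP,E,helix,-0.4425
TYR,E,helix,-0.1201
VAL,E,helix,-0.4376
ALA,E,sheet,-0.2798
ARG,E,sheet,0.3629
ASN,E,sheet,0.4591
ASP,E,sheet,0.3105
CYS,E,sheet,-0.0624
GLN,E,sheet,0.3624
GLU,E,sheet,0.2137
GLY,E,sheet,-0.2225
HIS,E,sheet,0.2536
ILE,E,sheet,-0.5343
LEU,E,sheet,-0.5343
LYS,E,sheet,0.1482
MET,E,sheet,-0.3967
PHE,E,sheet,-0.5831
PRO,E,sheet,-0.7566
SER,E,sheet,0.4951
THR,E,sheet,0.3338
TRP,E,sheet,-0.4425
TYR,E,sheet,-0.1201
VAL,E,sheet,-0.4376
ALA,E,other,-0.2798
ARG,E,other,0.3629
ASN,E,other,0.4591
ASP,E,other,0.3105
CYS,E,other,-0.0624
GLN,E,other,0.3624
GLU,E,other,0.2137
GLY,E,other,-0.0225
HIS,E,other,0.2536
ILE,E,other,-0.5343
LEU,E,other,-0.5343
LYS,E,other,0.1482
MET,E,other,-0.3967
PHE,E,other,-0.5831
PRO,E,other,-0.3566
SER,E,other,0.4951
THR,E,other,0.3338
TRP,E,other,-0.4425
TYR,E,other,-0.1201
VAL,E,other,-0.4376
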