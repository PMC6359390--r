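id,name,smiles
CIP,Ciprofloxacin,OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O
CLI,Clinafloxacin,OC(=O)c1cn(C2CC2)c2c(Cl)c(N3CCC(N)C3)c(F)cc2c1=O
DAN,Danofloxacin,CN1[C@@H]2CC[C@H]1CN(C2)c1cc2c(cc1F)c(=O)c(C(O)=O)cn2C1CC1
DIF,Difloxacin,OC(=O)c1cn(-c2ccc(F)cc2)c2cc(N3CCN(C)CC3)c(F)cc2c1=O
ENO,Enoxacin,CCn1cc(C(O)=O)c(=O)c2cc(F)c(N3CCNCC3)nc12
ENR,Enrofloxacin,OC(=O)c1cn(C2CC2)c2cc(N3CCN(CC)CC3)c(F)cc2c1=O
FLU,Flumequine,CC1CCc2cc(F)cc3c(=O)c(C(O)=O)cn1c23
GAR,Garenoxacin,C[C@@H]1NCc2cc(ccc21)-c1ccc2c(=O)c(C(O)=O)cn(C3CC3)c2c1OC(F)F
GAT,Gatifloxacin,COc1c(N2CCNC(C)C2)c(F)cc2c(=O)c(C(O)=O)cn(C3CC3)c12
LEV,Levofloxacin,C[C@H]1COc2c(N3CCN(C)CC3)c(F)cc3c(=O)c(C(O)=O)cn1c23
LOM,Lomefloxacin,CCn1cc(C(O)=O)c(=O)c2cc(F)c(N3CC(C)NCC3)c(F)c12
MAR,Marbofloxacin,CN1COc2c(N3CCN(C)CC3)c(F)cc3c(=O)c(C(O)=O)cn1c23
MOX,Moxifloxacin,COc1c(N2C[C@@H]3CCCN[C@@H]3C2)c(F)cc2c(=O)c(C(O)=O)cn(C3CC3)c12
NAD,Nadifloxacin,CC1CCc2c(N3CCC(O)CC3)c(F)cc3c(=O)c(C(O)=O)cn1c23
NAL,Nalidixic acid,CCn1cc(C(O)=O)c(=O)c2ccc(C)nc12
NOR,Norfloxacin,CCn1cc(C(O)=O)c(=O)c2cc(F)c(N3CCNCC3)cc12
ORB,Orbifloxacin,CC1CN(CC(C)N1)c1c(F)c(F)c2c(=O)c(C(O)=O)cn(C3CC3)c2c1F
OXO,Oxolinic acid,CCn1cc(C(O)=O)c(=O)c2cc3OCOc3cc12
PAZ,Pazufloxacin,C[C@H]1COc2c(C3(N)CC3)c(F)cc3c(=O)c(C(O)=O)cn1c23
PEF,Pefloxacin,CCn1cc(C(O)=O)c(=O)c2cc(F)c(N3CCN(C)CC3)cc12
PIP,Pipemidic acid,CCn1cc(C(O)=O)c(=O)c2cnc(N3CCNCC3)nc12
R-OFL,R-Ofloxacin,C[C@@H]1COc2c(N3CCN(C)CC3)c(F)cc3c(=O)c(C(O)=O)cn1c23
RUF,Rufloxacin,CN1CCN(CC1)c1c(F)cc2c(=O)c(C(O)=O)cn3CCSc1c23
SAR,Sarafloxacin,OC(=O)c1cn(-c2ccc(F)cc2)c2cc(N3CCNCC3)c(F)cc2c1=O
SPA,Sparfloxacin,CC1CN(CC(C)N1)c1c(F)c(N)c2c(=O)c(C(O)=O)cn(C3CC3)c2c1F
TOZ,Tosufloxacin,NC1CCN(C1)c1nc2c(cc1F)c(=O)c(C(O)=O)cn2-c1ccc(F)cc1F
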