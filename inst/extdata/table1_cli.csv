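compound_id,cr
CIP,73
CLI,100
DAN,63
DIF,<1
ENO,5
ENR,33
FLU,<1
GAR,92
GAT,15
LEV,<1
LOM,<1
MAR,<1
MOX,8
NAD,90
NAL,<1
NOR,<1
ORB,10
OXO,<1
PAZ,<1
PEF,<1
PIP,<1
R-OFL,<1
RUF,<1
SAR,<1
SPA,10
TOZ,<1
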