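compound_id,cr
CIP,100
CLI,52
DAN,76
DIF,1
ENO,39
ENR,57
FLU,72
GAR,56
GAT,52
LEV,-
LOM,25
MAR,19
MOX,25
NAD,49
NAL,77
NOR,28
ORB,58
OXO,36
PAZ,24
PEF,26
PIP,44
R-OFL,-
RUF,13
SAR,1
SPA,43
TOZ,6
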