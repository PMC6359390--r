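compound_id,N(>CH-),S(>CH-),N(Stereo),Shadow-YZ
CIP,1,0.187,0,40.61
CLI,2,0.031,1,45.23
DAN,3,0.918,2,48.22
DIF,0,0,0,55.14
ENO,0,0,0,38.28
ENR,1,0.186,0,42.55
FLU,1,0.096,1,35.64
GAR,3,-2.935,1,48.49
GAT,2,0.29,1,47.77
LEV,1,-0.158,1,42.71
LOM,1,0.074,1,43.80
MAR,0,0,0,42.93
MOX,3,0.887,2,47.48
NAD,2,-0.327,1,44.99
NAL,0,0,0,32.42
NOR,0,0,0,38.77
ORB,3,-0.379,2,46.85
OXO,0,0,0,32.34
PAZ,1,-0.172,1,42.21
PEF,0,0,0,39.69
PIP,0,0,0,36.79
R-OFL,1,-0.158,1,42.79
RUF,0,0,0,41.23
SAR,0,0,0,54.61
SPA,3,-0.104,2,47.87
TOZ,1,-0.169,1,53.28
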