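parameter,label,lower,upper
ANB,3,-Inf,3.2
ANB,1,3.2,5.7
ANB,2,5.7,Inf
SNB,2,-Inf,74.6
SNB,1,74.6,78.7
SNB,3,78.7,Inf
SNA,3,-Inf,79.4
SNA,1,79.4,83.2
SNA,2,83.2,Inf
ODI,3,-Inf,68.4
ODI,1,68.4,80.5
ODI,2,80.5,Inf
APDI,2,-Inf,77.6
APDI,1,77.6,85.2
APDI,3,85.2,Inf
FHI,3,-Inf,0.65
FHI,1,0.65,0.75
FHI,2,0.75,Inf
FMA,3,-Inf,26.8
FMA,1,26.8,31.4
FMA,2,31.4,Inf
MW,4,-Inf,0
MW,3,0,2
MW,1,2,4.5
MW,5,4.5,Inf
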