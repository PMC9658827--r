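residue	mean_distance	sd_distance
GLY256	4.44	0.21
THR272	5.53	0.61
SER273	5.58	0.09
PRO255	5.77	0.26
THR240	6.04	0.27
ARG266	6.29	0.70
PRO238	6.30	0.58
GLY274	6.33	0.23
ASP267	6.49	0.44
ARG76	6.58	0.55
GLY257	6.64	0.69
ASN270	7.04	0.79
THR275	7.59	0.45
VAL241	7.64	0.75
ILE239	7.74	0.25
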