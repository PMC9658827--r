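replicate	residue
replicate_1	PRO255
replicate_1	GLY256
replicate_2	ARG76
replicate_2	PRO238
replicate_2	ILE239
replicate_2	THR240
replicate_2	VAL241
replicate_2	ARG266
replicate_2	GLY256
replicate_2	GLY257
replicate_2	THR272
replicate_2	SER273
replicate_2	GLY274
replicate_3	ARG76
replicate_3	PRO238
replicate_3	ILE239
replicate_3	THR240
replicate_3	VAL241
replicate_3	ASP242
replicate_3	PRO255
replicate_3	GLY256
replicate_3	GLY257
replicate_3	ARG266
replicate_3	ASP267
replicate_3	ASN270
replicate_3	THR272
replicate_3	SER273
replicate_3	GLY274
replicate_3	THR275
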