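sample	positions	scale_factor
HeLa-S3	392	2.11
HepG2	295	1.26
K562	294	2.17
MCF-7	140	0.76
GM12878	416	1.44
HUVEC	267	1.40
H1-hESC	355	1.91
HSMM	16	0.49
HMEC	5	0.24
NHEK	202	1.53
NHLF	18	0.39
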