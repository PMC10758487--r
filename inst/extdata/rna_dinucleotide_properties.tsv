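property	AA	AC	AG	AU	CA	CC	CG	CU	GA	GC	GG	GU	UA	UC	UG	UU
stacking_energy	-0.93	-2.24	-2.08	-1.10	-2.11	-3.26	-2.36	-2.08	-2.35	-3.42	-3.26	-2.24	-1.33	-2.35	-2.11	-0.93
gc_content	0	0.5	0.5	0	0.5	1	1	0.5	0.5	1	1	0.5	0	0.5	0.5	0
purine_content	1	0.5	1	0.5	0.5	0	0.5	0	1	0.5	1	0.5	0.5	0	0.5	0
keto_content	0	0	0.5	0.5	0	0	0.5	0.5	0.5	0.5	1	1	0.5	0.5	1	1
eiip_mean	0.1260	0.1300	0.1033	0.12975	0.1300	0.1340	0.1073	0.13375	0.1033	0.1073	0.0806	0.10705	0.12975	0.13375	0.10705	0.1335
eiip_asymmetry	0	-0.0080	0.0454	-0.0075	0.0080	0	0.0534	0.0005	-0.0454	-0.0534	0	-0.0529	0.0075	-0.0005	0.0529	0
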