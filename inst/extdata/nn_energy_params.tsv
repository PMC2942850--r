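term	key1	key2	dg
stack	AU	AU	-1.05
stack	AU	CG	-2.2
stack	AU	GC	-2.2
stack	AU	GU	-1.075
stack	AU	UA	-1.05
stack	AU	UG	-1.075
stack	CG	AU	-2.2
stack	CG	CG	-3.1
stack	CG	GC	-3.1
stack	CG	GU	-1.875
stack	CG	UA	-2.2
stack	CG	UG	-1.875
stack	GC	AU	-2.2
stack	GC	CG	-3.1
stack	GC	GC	-3.1
stack	GC	GU	-1.875
stack	GC	UA	-2.2
stack	GC	UG	-1.875
stack	GU	AU	-1.075
stack	GU	CG	-1.875
stack	GU	GC	-1.875
stack	GU	GU	0.15
stack	GU	UA	-1.075
stack	GU	UG	0.15
stack	UA	AU	-1.05
stack	UA	CG	-2.2
stack	UA	GC	-2.2
stack	UA	GU	-1.075
stack	UA	UA	-1.05
stack	UA	UG	-1.075
stack	UG	AU	-1.075
stack	UG	CG	-1.875
stack	UG	GC	-1.875
stack	UG	GU	0.15
stack	UG	UA	-1.075
stack	UG	UG	0.15
hairpin	3	NA	5.4
hairpin	4	NA	5.6
hairpin	5	NA	5.7
hairpin	6	NA	5.4
hairpin	7	NA	6.0
hairpin	8	NA	5.5
hairpin	9	NA	6.4
hairpin	10	NA	6.5
bulge	1	NA	3.8
bulge	2	NA	2.8
bulge	3	NA	3.2
bulge	4	NA	3.6
bulge	5	NA	4.0
bulge	6	NA	4.4
internal	2	NA	1.5
internal	3	NA	1.6
internal	4	NA	1.7
internal	5	NA	1.8
internal	6	NA	2.0
internal	7	NA	2.2
internal	8	NA	2.3
internal	9	NA	2.4
internal	10	NA	2.5
multiloop	offset	NA	3.4
multiloop	branch	NA	0.4
multiloop	unpaired	NA	0.0
extrapolation	lxc	NA	1.0785
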