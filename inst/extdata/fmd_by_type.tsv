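# Genome-wide perfect-SSR overview from a published survey of the
# forest musk deer (Moschus berezovskii) genome (2.72 Gb assembly).
# Two per-type counts carry digit-grouping misprints in the published
# table; the values below are reconciled against the printed total,
# percentages and text (39,977 tetra; 96,262 penta).
type	n_loci	gc_percent	total_length_bp	relative_abundance	percentage
Mono	273518	1.72	3192531	100.38	40.19
Di	148175	37.14	2719558	53.40	21.77
Tri	122105	62.56	2077536	44.00	17.94
Tetra	39977	29.13	678452	14.41	5.87
Penta	96262	40.27	106801	35.33	14.14
Hexa	598	59.97	15420	0.22	0.09
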