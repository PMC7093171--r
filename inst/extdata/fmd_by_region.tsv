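# Per-type perfect-SSR counts and relative abundance (loci/Mb) in six
# genomic region classes, from a published survey of the forest musk
# deer genome. Region classes: five disjoint base classes plus the TE
# overlay (TE-resident loci also carry a base class).
type	region	n_loci	relative_abundance
Mono	FIVE_UTR	115	59.10
Mono	CDS	26	0.76
Mono	INTRON	72591	104.31
Mono	THREE_UTR	598	78.20
Mono	TE	58987	49.01
Mono	INTERGENIC	135726	91.61
Di	FIVE_UTR	60	30.83
Di	CDS	16	0.47
Di	INTRON	45758	54.79
Di	THREE_UTR	316	41.32
Di	TE	27997	22.93
Di	INTERGENIC	89153	62.54
Tri	FIVE_UTR	178	91.47
Tri	CDS	2419	70.38
Tri	INTRON	36275	43.43
Tri	THREE_UTR	83	10.85
Tri	TE	6789	5.35
Tri	INTERGENIC	53607	36.18
Tetra	FIVE_UTR	38	19.53
Tetra	CDS	23	0.67
Tetra	INTRON	13458	16.11
Tetra	THREE_UTR	56	7.32
Tetra	TE	12619	8.58
Tetra	INTERGENIC	28975	19.56
Penta	FIVE_UTR	9	4.62
Penta	CDS	18	0.52
Penta	INTRON	32870	39.36
Penta	THREE_UTR	19	2.48
Penta	TE	3683	2.94
Penta	INTERGENIC	50814	34.30
Hexa	FIVE_UTR	5	2.57
Hexa	CDS	86	2.50
Hexa	INTRON	173	0.21
Hexa	THREE_UTR	2	0.13
Hexa	TE	74	0.05
Hexa	INTERGENIC	791	0.56
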