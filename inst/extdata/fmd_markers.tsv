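# Tetranucleotide marker panel genotyped on 36 captive forest musk
# deer: per-locus allele counts and diversity statistics from the
# published survey. The 21 retained loci plus the one locus (LS-55-1)
# discarded for deviating from Hardy-Weinberg equilibrium (P < 0.01);
# only k and Ar were published for the discarded locus.
locus	repeat_unit	N	k	Ho	He	Ar	PIC	hwe_p	discarded
LS-2-1	(GCAG)10	36	6	0.385	0.65	6.000	0.593	0.03	FALSE
LS-6-1	(GATG)8	36	3	0.538	0.555	3.000	0.484	0.376	FALSE
LS-7-1	(AGGA)8	36	2	0.154	0.145	2.000	0.132	0.884	FALSE
LS-8-1	(AGAC)8	36	5	0.654	0.675	5.000	0.598	0.311	FALSE
LS-9-1	(ATAG)8	36	3	0.192	0.278	2.895	0.255	0.054	FALSE
LS-12-3	(CAGA)8	36	3	0.538	0.679	3.00	0.592	0.097	FALSE
LS-13-1	(AGAA)8	36	6	0.615	0.655	6.000	0.582	0.253	FALSE
LS-14-2	(TGCG)8	36	6	0.692	0.735	5.997	0.683	0.562	FALSE
LS-16-1	(AGAC)8	36	4	0.577	0.508	3.990	0.454	0.181	FALSE
LS-17-1	(TATG)8	36	4	0.615	0.63	4.000	0.548	0.503	FALSE
LS-18-1	(CCAT)8	36	3	0.577	0.562	2.993	0.472	0.391	FALSE
LS-24-1	(TTGG)7	36	4	0.615	0.613	4.000	0.555	0.607	FALSE
LS-27-1	(ATGG)7	36	4	0.308	0.278	3.995	0.257	0.54	FALSE
LS-28-1	(ATCC)7	36	3	0.154	0.147	3.000	0.138	0.883	FALSE
LS-29-1	(TTTA)7	36	3	0.346	0.386	3.000	0.343	0.351	FALSE
LS-30-1	(ATCC)7	36	2	0.231	0.208	1.968	0.183	0.722	FALSE
LS-31-1	(ATGG)7	36	2	0.154	0.208	2.000	0.183	0.274	FALSE
LS-35-1	(TGGA)7	36	2	0.115	0.111	1.965	0.103	0.94	FALSE
LS-47-1	(CCAA)15	36	4	0.615	0.571	4.000	0.512	0.319	FALSE
LS-50-1	(TCCA)12	36	4	0.5	0.455	3.995	0.397	0.235	FALSE
LS-56-1	(CATA)12	36	3	0.308	0.305	3.000	0.277	0.656	FALSE
LS-55-1	(CATA)14	36	7	NA	NA	7.00	NA	NA	TRUE
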