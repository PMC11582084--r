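taxon	group	haploid_n	diploid_2n	locality	formula	genome_mbp	nm	nsm	nst	nt	fn
Amoimyrmex striatus	leafcutter	11	22	Brazil	20 m + 2sm	342.3	10	1	0	0	44
Amoimyrmex bruchi	leafcutter	11	22	Argentina	20 m + 2sm	298.8	10	1	0	0	44
Amoimyrmex silvestrii	leafcutter	11	22	Argentina	20 m + 2sm	311.37	10	1	0	0	44
Atta bisphaerica	leafcutter	11	22	Brazil	12 m + 6sm + 4st	NA	6	3	2	0	40
Atta colombica	leafcutter	11	22	Panama	12 m + 6sm + 4st	298.8	6	3	2	0	40
Atta laevigata	leafcutter	11	22	Brazil	12 m + 6sm + 4st	322.74	6	3	2	0	40
Atta sexdens	leafcutter	11	22	Brazil	12 m + 6sm + 4st	322.74	6	3	2	0	40
Atta robusta	leafcutter	11	22	Brazil	18 m + 2sm + 2st	332.52	9	1	1	0	44
Atta sexdens	leafcutter	11	22	French Guiana	18 m + 2sm + 2st	322.74	9	1	1	0	44
Acromyrmex ambiguus	leafcutter	19	38	Uruguay	2 m + 6sm + 16st + 14 t	322.74	1	3	8	7	62
Acromyrmex ambiguus	leafcutter	19	38	Brazil	14 m + 12sm + 8st + 4 t	NA	7	6	4	2	68
Acromyrmex crassispinus	leafcutter	19	38	Brazil	2 m + 6sm + 16st + 14 t	332.52	1	3	8	7	62
Acromyrmex crassispinus	leafcutter	19	38	Brazil	12 m + 20sm + 4st + 2 t	332.52	6	10	2	1	74
Acromyrmex heyeri	leafcutter	19	38	Uruguay	2 m + 6sm + 16st + 14 t	NA	1	3	8	7	62
Acromyrmex lundi	leafcutter	19	38	Brazil	10 m + 14sm + 10st + 4 t	NA	5	7	5	2	72
Acromyrmex nigrosetosus	leafcutter	19	38	Brazil	12 m + 14sm + 10st + 2 t	342.3	6	7	5	1	74
Acromyrmex hispidus	leafcutter	19	38	Uruguay	2 m + 6sm + 16st + 14 t	NA	1	3	8	7	62
Acromyrmex molestans	leafcutter	19	38	Brazil	2 m + 6sm + 16st + 14 t	332.52	1	3	8	7	62
Acromyrmex molestans	leafcutter	19	38	Brazil	10 m + 10sm + 16st + 2 t	332.52	5	5	8	1	74
Acromyrmex subterraneus	leafcutter	19	38	Brazil	2 m + 6sm + 16st + 14 t	342.3	1	3	8	7	62
Acromyrmex subterraneus	leafcutter	19	38	Brazil	14 m + 18sm + 4st + 2 t	342.3	7	9	2	1	74
Acromyrmex balzani	leafcutter	19	38	Brazil, French Guiana	12 m + 10sm + 14st + 2 t	361.86	6	5	7	1	74
Acromyrmex coronatus	leafcutter	19	38	Brazil	12 m + 8sm + 16st + 2 t	332.52	6	4	8	1	74
Acromyrmex disciger	leafcutter	19	38	Brazil	10 m + 12sm + 14st + 2 t	322.74	5	6	7	1	74
Acromyrmex echinatior	leafcutter	19	38	Brazil	8 m + 6sm + 14st + 10 t	335	4	3	7	5	66
Acromyrmex niger	leafcutter	19	38	Brazil	12 m + 14sm + 10st + 2 t	352.08	6	7	5	1	74
Acromyrmex rugosus	leafcutter	19	38	Brazil	16 m + 12sm + 8st + 2 t	342.3	8	6	4	1	74
Acromyrmex aspersus	leafcutter	19	38	Brazil	8 m + 10sm + 16st + 4 t	NA	4	5	8	2	72
Acromyrmex ameliae	leafcutter	18	36	Brazil	2 m + 8sm + 20st + 6 t	NA	1	4	10	3	66
Acromyrmex brunneus	leafcutter	19	38	Brazil	2 m + 6sm + 20st + 10 t	332.52	1	3	10	5	66
Mycetomoellerius holmgreni	outgroup	10	20	Brazil	20 m	322.74	10	0	0	0	40
Mycetomoellerius iheringi	outgroup	10	20	Brazil	20 m	391.2	10	0	0	0	40
Trachymyrmex septentrionalis	outgroup	10	20	Panama	20 m	244.5	10	0	0	0	40
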