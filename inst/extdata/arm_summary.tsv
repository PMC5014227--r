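# Per-arm assembly summary of a 15622-clone gene-bearing BAC sequencing resource (barley cv. Morex; nodes >= 200 bp)
# Columns: label = chromosome-arm assignment (C = centromeric overlap, NA = unassigned); averages are unweighted means over member BACs.
label	n_bacs	avg_nodes	total_len	avg_len	avg_n50	avg_l50	unique_hc	unique_lc
1H	1959	19.5	209800854	107096	23697	2.8	2866	3502
2HS	1048	18.5	111465824	106361	24703	2.7	1486	1935
2HL	1391	19.1	149179441	107246	22978	2.7	2241	2529
3HS	862	18.2	92368717	107156	26301	2.6	1242	1704
3HL	1389	18.8	148465120	106886	24223	2.7	2132	2576
4HS	862	17.9	94522065	109654	26577	2.6	1048	1442
4HC	60	15.8	5866127	97769	28999	2.2	20	40
4HL	1100	18.7	120519518	109563	25756	2.7	1536	1740
5HS	640	19.1	69074495	107929	24696	2.8	812	1207
5HL	1623	20.1	173282123	106767	22285	2.9	2777	3288
6HS	823	19.7	87025477	105742	22248	2.8	1070	1624
6HL	1113	19.3	120662552	108412	23922	2.8	1610	1942
7HS	1196	19	129484046	108264	24580	2.7	1770	2496
7HL	1150	20.1	122082348	106159	23221	2.8	1734	2182
NA	406	41.6	63956654	157529	16942	5.2	994	1287
All	15622	19.7	1697755361	108677	23906	2.8	15707	19330
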