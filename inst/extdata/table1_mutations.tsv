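sample_id	location	gene	function_class	damaging_tally	chrom	start	ref	obs
32	Exonic; splicing	GPS2	splice_site	NA	chr17	7217225	C	T
41	Exonic; splicing	KDM6A	frameshift	NA	chrX	44969494	-	GG
17	Exonic	MLL3	nonsynonymous	4/4	chr7	151859899	G	A
16	Exonic	MLL3	nonsynonymous	2/4	chr7	151860230	G	C
16	Exonic	MLL3	nonsynonymous	1/4	chr7	151877127	G	T
21	Exonic	MLL3	nonsynonymous	4/4	chr7	151879265	G	T
21	Exonic	MLL3	stopgain	NA	chr7	151900023	A	T
13	Exonic	MLL3	stopgain	NA	chr7	151874686	G	A
21	Exonic	MLL3	nonsynonymous	3/4	chr7	151875073	G	A
30	Exonic	MLL3	nonsynonymous	3/3	chr7	151927021	C	A
28	Exonic	MLL3	nonsynonymous	1/4	chr7	151919690	C	T
33	Exonic	MLL3	nonsynonymous	3/4	chr7	151970877	G	A
20	Exonic	MLL3	nonsynonymous	2/4	chr7	151945568	C	T
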