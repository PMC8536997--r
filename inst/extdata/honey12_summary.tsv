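sample_id	province	n_reads	n_retained	pct_retained	n_alleles	n_private	pct_private	n_novel	n_novel_private
H1	Bologna	173064	149678	86.4	17	8	47.1	9	7
H2	Reggio Emilia	75454	72027	95.4	13	4	30.8	5	3
H3	Piacenza	414002	269785	64.8	40	16	40.0	13	11
H4	Reggio Emilia	84307	82056	97.3	14	2	14.3	5	0
H5	Reggio Emilia	397333	296982	74.7	20	7	35.0	5	3
H6	Ferrara	34350	33503	97.5	13	3	23.1	7	3
H7	Piacenza	99979	48369	48.3	23	11	47.8	12	11
H8	Bologna	41741	37431	89.7	17	4	23.5	3	1
H9	Piacenza	97735	73994	75.7	33	13	39.4	16	11
H10	Rimini	70307	53728	75.1	61	41	67.2	40	37
H11	Piacenza	35183	29865	84.9	10	2	20.0	3	1
H12	Piacenza	1341	1220	91.0	10	3	30.0	0	0
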