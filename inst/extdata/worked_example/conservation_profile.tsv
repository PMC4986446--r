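# cugusage 0.1.0; thresholds=0.9/0.8/0.5; flank=15; window=3; lambda=0.5; score=w3; min_sites=1; margin=3
global_column	family_id	local_column	n_retained	gap_fraction	score_w0	score_w3	modal_residue	modal_fraction	has_leu	has_ser
3	toy	3	5	0	1	1	L	1	TRUE	FALSE
9	toy	9	6	0	1	1	L	1	TRUE	FALSE
15	toy	15	8	0	1	0.930507081449338	L	1	TRUE	FALSE
18	toy	18	7	0	0.135025614489475	0.567512807244737	S	0.142857142857143	FALSE	TRUE
21	toy	21	5	0	1	0.950936487006976	S	1	FALSE	TRUE
27	toy	27	6	0	1	1	S	1	FALSE	TRUE
33	toy	33	8	0	1	1	S	1	FALSE	TRUE
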