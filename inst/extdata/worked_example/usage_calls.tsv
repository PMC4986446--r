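# cugusage 0.1.0; thresholds=0.9/0.8/0.5; flank=15; window=3; lambda=0.5; score=w3; min_sites=1; margin=3
species_id	n_cug	leu_count_0.9	leu_pct_0.9	ser_count_0.9	ser_pct_0.9	leu_count_0.8	leu_pct_0.8	ser_count_0.8	ser_pct_0.8	leu_count_0.5	leu_pct_0.5	ser_count_0.5	ser_pct_0.5	call	decisive_threshold	evidence_ratio
aycuA	2	0	0	2	100	0	0	2	100	0	0	2	100	aycu	0.9	Inf
aycuB	2	0	0	2	100	0	0	2	100	0	0	2	100	aycu	0.9	Inf
aycuC	1	0	0	1	100	0	0	1	100	0	0	1	100	aycu	0.9	Inf
aycuD	1	0	0	0	0	0	0	0	0	0	0	1	100	aycu	0.5	Inf
stdA	2	2	100	0	0	2	100	0	0	2	100	0	0	standard	0.9	Inf
stdB	2	2	100	0	0	2	100	0	0	2	100	0	0	standard	0.9	Inf
stdC	1	1	100	0	0	1	100	0	0	1	100	0	0	standard	0.9	Inf
stdD	0	0	0	0	0	0	0	0	0	0	0	0	0	no_data	NA	NA
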