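# cugusage 0.1.0; thresholds=0.9/0.8/0.5; flank=15; window=3; lambda=0.5; score=w3; min_sites=1; margin=3
species	aycuA	aycuB	aycuC	aycuD	stdA	stdB	stdC	stdD
aycuA	2	2	1	0	0	0	0	0
aycuB	2	2	1	0	0	0	0	0
aycuC	1	1	1	0	0	0	0	0
aycuD	0	0	0	1	0	0	0	0
stdA	0	0	0	0	2	2	1	0
stdB	0	0	0	0	2	2	1	0
stdC	0	0	0	0	1	1	1	0
stdD	0	0	0	0	0	0	0	0
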