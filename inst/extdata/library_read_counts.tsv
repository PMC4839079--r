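sample_id	stage	rnaseq_trimmed_reads	rnaseq_unique_mapping_pct	srna_trimmed_reads	srna_distinct_reads
S1a	S1	70216602	39.442	10425301	1813927
S1b	S1	75697405	38.307	10247910	2332967
S1c	S1	55646245	34.298	9892496	2983585
S2a	S2	66434325	42.742	10707291	3092207
S2b	S2	66122827	43.012	9718833	2572135
S2c	S2	73711917	42.240	10154174	3174185
S3a	S3	71321690	44.759	10789357	2908387
S3b	S3	70400647	50.624	10664717	3063376
S3c	S3	58681677	40.775	9939297	4006577
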