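rank	id	symbol	level_value
1	ENSP00000304565	RAB31	0.9105
2	ENSP00000421799	ENSG00000257184	0.8868
3	ENSP00000469872	RAB4B-EGLN2	0.8500
4	ENSP00000283921	HOXA10	0.8289
5	ENSP00000385586	HOXD12	0.8184
6	ENSP00000348429	ACSL5	0.8184
7	ENSP00000256953	RERG	0.8105
8	ENSP00000341032	WNT7B	0.8053
9	ENSP00000321805	RIT2	0.7763
10	ENSP00000285735	RHOC	0.7763
11	ENSP00000282397	FLT1	0.7763
12	ENSP00000264711	DNAJC27	0.7737
13	ENSP00000339787	ACSL4	0.7737
14	ENSP00000357306	RIT1	0.7684
15	ENSP00000301068	RHEBL1	0.7684
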