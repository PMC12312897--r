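name	seq	frame_id	direction	name_position
c891F	TACACGAGCATATTTTACATC	COI	forward	891
c1472R	GCTGGTGGTAAATTTTGATATC	COI	reverse	1472
t412F	CCGGACTGAAGGTTATCGCTTG	TpiGenomic	forward	412
t1140R	GCGGAAGCATTCGCTGACAACC	TpiGenomic	reverse	1140
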