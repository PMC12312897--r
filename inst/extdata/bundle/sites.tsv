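site_id	frame_id	position	allowed	role
mCOI1164D	COI	1164	AGT	strain_diagnostic
mCOI1287R	COI	1287	AG	group_defining
gTpi129Y	TpiGenomic	129	CT	informative
gTpi144R	TpiGenomic	144	AG	informative
gTpi165Y	TpiGenomic	165	CT	informative
gTpi168Y	TpiGenomic	168	CT	informative
gTpi180B	TpiGenomic	180	CGT	informative
gTpi183Y	TpiGenomic	183	CT	strain_diagnostic
gTpi192Y	TpiGenomic	192	CT	group_defining
gTpi198Y	TpiGenomic	198	CT	group_defining
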