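label	marker	strain	site_id	base
R_COIB	COIB	R	mCOI1164D	T
R_COIB	COIB	R	mCOI1287R	A
CSh1	COIB	C	mCOI1164D	A
CSh1	COIB	C	mCOI1287R	A
CSh2	COIB	C	mCOI1164D	A
CSh2	COIB	C	mCOI1287R	G
CSh3	COIB	C	mCOI1164D	G
CSh3	COIB	C	mCOI1287R	A
CSh4	COIB	C	mCOI1164D	G
CSh4	COIB	C	mCOI1287R	G
AfrCa1	TpiE4	C	gTpi129Y	C
AfrCa1	TpiE4	C	gTpi144R	G
AfrCa1	TpiE4	C	gTpi165Y	C
AfrCa1	TpiE4	C	gTpi168Y	C
AfrCa1	TpiE4	C	gTpi180B	G
AfrCa1	TpiE4	C	gTpi183Y	C
AfrCa1	TpiE4	C	gTpi192Y	C
AfrCa1	TpiE4	C	gTpi198Y	C
AfrCa2	TpiE4	C	gTpi129Y	C
AfrCa2	TpiE4	C	gTpi144R	G
AfrCa2	TpiE4	C	gTpi165Y	C
AfrCa2	TpiE4	C	gTpi168Y	C
AfrCa2	TpiE4	C	gTpi180B	G
AfrCa2	TpiE4	C	gTpi183Y	C
AfrCa2	TpiE4	C	gTpi192Y	T
AfrCa2	TpiE4	C	gTpi198Y	T
AfrRa1	TpiE4	R	gTpi129Y	T
AfrRa1	TpiE4	R	gTpi144R	A
AfrRa1	TpiE4	R	gTpi165Y	C
AfrRa1	TpiE4	R	gTpi168Y	T
AfrRa1	TpiE4	R	gTpi180B	T
AfrRa1	TpiE4	R	gTpi183Y	T
AfrRa1	TpiE4	R	gTpi192Y	C
AfrRa1	TpiE4	R	gTpi198Y	C
AfrRa2	TpiE4	R	gTpi129Y	C
AfrRa2	TpiE4	R	gTpi144R	G
AfrRa2	TpiE4	R	gTpi165Y	T
AfrRa2	TpiE4	R	gTpi168Y	T
AfrRa2	TpiE4	R	gTpi180B	T
AfrRa2	TpiE4	R	gTpi183Y	T
AfrRa2	TpiE4	R	gTpi192Y	C
AfrRa2	TpiE4	R	gTpi198Y	C
AfrRa3	TpiE4	R	gTpi129Y	C
AfrRa3	TpiE4	R	gTpi144R	G
AfrRa3	TpiE4	R	gTpi165Y	T
AfrRa3	TpiE4	R	gTpi168Y	T
AfrRa3	TpiE4	R	gTpi180B	G
AfrRa3	TpiE4	R	gTpi183Y	T
AfrRa3	TpiE4	R	gTpi192Y	C
AfrRa3	TpiE4	R	gTpi198Y	C
WH_C_consensus	TpiE4	C	gTpi165Y	C
WH_C_consensus	TpiE4	C	gTpi168Y	C
WH_C_consensus	TpiE4	C	gTpi183Y	C
WH_R_consensus	TpiE4	R	gTpi165Y	T
WH_R_consensus	TpiE4	R	gTpi168Y	T
WH_R_consensus	TpiE4	R	gTpi183Y	T
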