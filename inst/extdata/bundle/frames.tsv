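# frame_id	gene_offset	origin_note
frame_id	gene_offset	origin_note
COI	0	synthetic stand-in COI gene frame; position numerals follow the mCOI site names (mCOI1164 at position 1164); amplicon c891F..c1472R
TpiGenomic	411	synthetic stand-in Tpi amplicon frame; position 1 is the 5' base of primer t412F; site numerals (gTpi129..gTpi198) are frame coordinates; published primer numerals are full-gene coordinates (anchor = numeral - 411); exon 4 spans 101..210, intron 4 begins at 211
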