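sample_id	fwd_barcode	rev_barcode	fwd_primer	rev_primer	sponge	medium	surface	day	colonies	role	plate_group
AA_inoc	CCCCGCGG	NA	GTTYGATYMTGGCTCAG	TGCTGCCTCCCGTAGGAGT	AA	none	none	0	NA	inoculum	AA_inoc
AA_MA_agar_d15	TACCAGGT	NA	GTTYGATYMTGGCTCAG	TGCTGCCTCCCGTAGGAGT	AA	MA	agar	15	120	scraped	AA_MA_agar_d15
PG1_C01	GAGGACGC	TGGTCCGG	GTTYGATYMTGGCTCAG	TGCTGCCTCCCGTAGGAGT	AA	MA	agar	30	NA	colony	PG1
PG1_C02	GAGGACGC	CGGAATAG	GTTYGATYMTGGCTCAG	TGCTGCCTCCCGTAGGAGT	AA	MA	agar	30	NA	colony	PG1
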