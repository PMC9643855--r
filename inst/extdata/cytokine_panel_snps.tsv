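rsid	gene	ref_allele	alt_allele	genomic_location	annotation
rs1800587	IL1A	G	A	2:112785383	upstream transcript variant
rs1800796	IL6	G	C	7:22726627	non-coding transcript variant, intron variant
rs361525	TNFA	G	A	6:31575324	upstream transcript variant
rs1800629	TNFA	G	A	6:31575254	upstream transcript variant
rs2069705	IFNG	G	A	12:68161231	upstream transcript variant
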