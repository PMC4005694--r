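# tRNA isoacceptor inventory for Methanothermobacter thermautotrophicus
# strain deltaH (GenBank NC_000916.1), serine and arginine families.
# The tRNA-Ser-GGA gene is duplicated (copy_number 2).
# codons: explicit decoded codons (comma separated) or "auto" to apply
# the default wobble rules to the anticodon.
anticodon	amino_acid	copy_number	codons
GGA	S	2	TCC,TCT
TGA	S	1	TCA,TCG
GCT	S	1	AGC,AGT
GCG	R	1	CGC,CGT
TCG	R	1	CGA,CGG
CCT	R	1	AGG
TCT	R	1	AGA
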