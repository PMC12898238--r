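contig	pos	ref	alt	id	significance
chr17	31155982	G	A	rs1263745475	Pathogenic
chr17	31155981	A	G	rs1131691100	Pathogenic
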