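chromosome_class	heterozygous	homozygous	nonsynonymous	synonymous	utr	intronic	intergenic
Autosomes	4880874	4527169	25079	38233	42930	2878903	6422898
X	0	245769	444	701	986	50877	192761
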