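library	read_length	insert	runs	reads	mapped	analyzed	coverage
Fragment	50	-	8	2648128521	1976720560	1974496337	33.4
Mate-pair A	25x2	600-800	2	906783481	621175871	355589008	3.4
Mate-pair B	25x2	800-1000	2	1335583547	814866634	508168736	4.8
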