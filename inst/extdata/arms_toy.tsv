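chrom	arm	start	end
1	p	1	1000000
1	q	1000001	2000000
22	p	1	400000
22	q	400001	1000000
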