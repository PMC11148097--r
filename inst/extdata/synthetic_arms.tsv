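chrom	arm	start	end
chr1	1p	0	50000000
chr1	1q	50000000	100000000
chr2	2p	0	50000000
chr2	2q	50000000	100000000
chr3	3p	0	50000000
chr3	3q	50000000	100000000
chr4	4p	0	50000000
chr4	4q	50000000	100000000
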