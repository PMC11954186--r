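chrom	length	bases	mean
total	3100000000	2046000000	0.66
chr1	248956422	995825688	4.00
MT	16569	10936	0.66
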