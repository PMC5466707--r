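strain	chrom_length_bp	gap_length_bp	gap_number
Zhanggu_v1	399854594	26817695	31942
Zhanggu_v2	415979272	28962873	34452
Yugu_v1	401300876	4616102	6171
Yugu_v2	402520233	2175332	3297
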