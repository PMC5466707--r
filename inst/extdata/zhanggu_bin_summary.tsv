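chrom	length_bp	n_bins	linkage_cM	n_snps
chr1	44603498	408	167.117	42624
chr2	51761675	491	224.647	89674
chr3	54090027	396	221.738	81236
chr4	43349090	348	168.232	27932
chr5	49560508	480	267.52	60305
chr6	36928436	203	152.1	30946
chr7	37743793	242	168.48	56045
chr8	38066565	283	205.431	58149
chr9	59875680	586	352.58	36503
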