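chrom	length_morgan
chr1	2.863
chr2	2.686
chr3	2.234
chr4	2.146
chr5	2.041
chr6	1.921
chr7	1.874
chr8	1.68
chr9	1.664
chr10	1.81
chr11	1.582
chr12	1.747
chr13	1.258
chr14	1.208
chr15	1.419
chr16	1.34
chr17	1.285
chr18	1.175
chr19	1.078
chr20	1.083
chr21	0.628
chr22	0.741
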