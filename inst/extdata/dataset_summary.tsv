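metric	value
raw_reads	14919026
unique_tags	161288
clean_reads	9320178
ncrna_removed_reads	2679012
mapped_reads	4542396
mapped_unique_tags	25538
conserved_mirnas	237
conserved_families	105
duplex_pairs	120
length_21_23_percent	54.8
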