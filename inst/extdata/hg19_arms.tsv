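chrom	arm
chr1	p
chr1	q
chr2	p
chr2	q
chr3	p
chr3	q
chr4	p
chr4	q
chr5	p
chr5	q
chr6	p
chr6	q
chr7	p
chr7	q
chr8	p
chr8	q
chr9	p
chr9	q
chr10	p
chr10	q
chr11	p
chr11	q
chr12	p
chr12	q
chr13	q
chr14	q
chr15	q
chr16	p
chr16	q
chr17	p
chr17	q
chr18	p
chr18	q
chr19	p
chr19	q
chr20	p
chr20	q
chr21	q
chr22	q
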