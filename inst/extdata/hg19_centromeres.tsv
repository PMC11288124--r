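chr1	121535434	124535434
chr2	92326171	95326171
chr3	90504854	93504854
chr4	49660117	52660117
chr5	46405641	49405641
chr6	58830166	61830166
chr7	58054331	61054331
chr8	43838887	46838887
chr9	47367679	50367679
chr10	39254935	42254935
chr11	51644205	54644205
chr12	34856694	37856694
chr13	16000000	19000000
chr14	16000000	19000000
chr15	17000000	20000000
chr16	35335801	38335801
chr17	22263006	25263006
chr18	15460898	18460898
chr19	24681782	27681782
chr20	26369569	29369569
chr21	11288129	14288129
chr22	13000000	16000000
chrX	58632012	61632012
chrY	10104553	13104553
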