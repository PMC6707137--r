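chr1	48000000	52000000	LRLD_1
chr2	86000000	100500000	LRLD_2
chr2	134500000	138000000	LRLD_3
chr2	183000000	190000000	LRLD_4
chr3	47500000	50000000	LRLD_5
chr3	83500000	87000000	LRLD_6
chr3	89000000	97500000	LRLD_7
chr5	44500000	50500000	LRLD_8
chr5	98000000	100500000	LRLD_9
chr5	129000000	132000000	LRLD_10
chr5	135500000	138500000	LRLD_11
chr6	25500000	33500000	LRLD_12
chr6	57000000	64000000	LRLD_13
chr6	140000000	142500000	LRLD_14
chr7	55000000	66000000	LRLD_15
chr8	8000000	12000000	LRLD_16
chr8	43000000	50000000	LRLD_17
chr8	112000000	115000000	LRLD_18
chr10	37000000	43000000	LRLD_19
chr11	46000000	57000000	LRLD_20
chr11	87500000	90500000	LRLD_21
chr12	33000000	40000000	LRLD_22
chr12	109500000	112000000	LRLD_23
chr20	32000000	34500000	LRLD_24
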