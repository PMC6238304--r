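name	analysis	role	sequence	reported_length	reported_gc	reported_tm	reported_amplicon_size
DPKup	XL-PCR	outer	GTTATCCCAGAAGGCTTTGCAGGCTTCA	28	50.0	67.8	5100
DPKlow	XL-PCR	outer	GCCGACTGAGCCCTGGGAGGTAGGTA	26	65.4	71.1	5100
2D6dupl-F	XL-PCR	outer	CCTGGGAAGGCCCCATGGAAG	21	66.7	65.5	3500
2D6dupl-R	XL-PCR	outer	CAGTTACGGCAGTGGTCAGCT	21	57.1	63.2	3500
5'2D6*5	XL-PCR	outer	CACCAGGCACCTGTACTCCTC	21	61.9	62.7	3500
3'2D6*5	XL-PCR	outer	CAGGCATGAGCTAAGGCACCCAGAC	25	60.0	67.9	3500
5'2D6Int2	XL-PCR	nested	TTTTGCACTGTGGGTCCTC	19	52.6	58.5	1101
3'2D6Int2	XL-PCR	nested	CAAGGTGGACACGGAGAAG	19	57.9	58.4	1101
5'2D6Ex1	DSP	nested	GCACAGTCAACACAGCAGGT	20	55.0	61.7	503
3'2D6Ex1	DSP	nested	AATGCCCTTCTCCAGGAAGT	20	50.0	59.2	503
5'2D6Ex2	DSP	nested	TTCCTCCATCACAGAAGGTG	20	50.0	57.4	501
3'2D6Ex2	DSP	nested	CTCCCTAGTGCAGGTGGTTT	20	55.0	59.9	501
5'2D6Ex34	DSP	nested	GTCTTCCCTGAGTGCAAAGG	20	55.0	59.1	754
3'2D6Ex34	DSP	nested	AGTGGGGTCTCCTGGAATG	19	57.9	58.9	754
5'2D6Ex56	DSP	nested	GAGGGACTTGGTGAGGTCAG	20	60.0	60.0	794
3'2D6Ex56	DSP	nested	GACACTCCTTCTTGCCTCCT	20	55.0	59.6	794
5'2D6Ex7	DSP	nested	ATGAACTTTGCTGGGACACC	20	50.0	59.0	505
3'2D6Ex7	DSP	nested	CCAGCCCTGCCTATACTCTG	20	60.0	59.9	505
5'2D6Ex89	DSP	nested	TCTAGTGGGGAGACAAACCAG	21	52.4	59.3	802
3'2D6Ex89	DSP	nested	CTGAGGAGGATGATCCCAAC	20	55.0	57.7	802
5'2D6C100T	ASO	nested	CCTGGTGGACCTGATGCA	18	61.1	59.5	73
3'2D6C100T	ASO	nested	CCCGGGCAGTGGCA	14	78.6	58.7	73
2D6C100T_WT	ASO	probe_wt	CCTGGTGGGTAGCGTG	16	69.0	51.1	NA
2D6C100T_MT	ASO	probe_mut	CCTGGTGAGTAGCGTG	16	63.0	48.5	NA
5'2D6G1846A	ASO	nested	GACCCCTTACCCGCATCTC	19	63.2	60.1	73
3'2D6G1846A	ASO	nested	GCTCACGGCTTTGTCCAAGA	20	55.0	61.5	73
2D6G1846A_WT	ASO	probe_wt	CCCCCAGGACGCC	13	85.0	48.0	NA
2D6G1846A_MT	ASO	probe_mut	CCCCCAAGACGCC	13	77.0	46.0	NA
5'2D6C2850T	ASO	nested	CCTGAGAGCAGCTTCAATGATGA	23	47.8	61.3	67
3'2D6C2850T	ASO	nested	CCATCCCGGCAGAGAACAG	19	63.2	60.7	67
2D6C2850T_WT	ASO	probe_wt	ACTATGCGCAGGTTC	15	53.0	41.9	NA
2D6C2850T_MT	ASO	probe_mut	CACTATGCACAGGTTC	16	50.0	43.4	NA
5'2D6G4180C	ASO	nested	CCACCATGGTGTCTTTGCTTTC	22	50.0	60.9	67
3'2D6G4180C	ASO	nested	GCACAGCACAAAGCTCATAGG	21	52.4	60.4	67
2D6G4180C_WT	ASO	probe_wt	CTGGTGAGCCCATCC	15	67.0	47.4	NA
2D6G4180C_MT	ASO	probe_mut	CTGGTGACCCCATCC	15	67.0	47.4	NA
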