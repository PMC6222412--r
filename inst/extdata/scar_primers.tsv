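name	sequence	expected_size	species
CM F2	GGCCCCAAACAGTGTATCTAC	339	C. militaris
CM R2	CCGGTGCGAGTTGGCGTACTA	339	C. militaris
CM F3	CAACCCTTTGTGAACATACCT	102	C. militaris
CM R3	GTAGATACACTGTTTGGGGCC	102	C. militaris
CP F2	GACCCCAAACTCTGTTTCTAG	244	C. pruinosa
CP R2	CCCCGCGAGGAGGGGTCGAGT	244	C. pruinosa
CP F1	ACTCGACCCCTCCTCGCGGGG	116	C. pruinosa
CP R1	GTCCCGGTGCGACTGGTGTG	116	C. pruinosa
IC F1	ACGCAACCCTGTATCCATCAGT	337	I. cicadae
IC R1	TTCCCGGTGCGACTGGTTGT	337	I. cicadae
IC F3	ACCCTTCTGTGAACCTACGCATC	137	I. cicadae
IC R3	GATTCAGCGAGACTGATGGAT	137	I. cicadae
IT F4	CCTTCTGTGAACCTACCCATA	132	I. tenuipes
IT R3	GAGCGGCTCACAGATACAGG	132	I. tenuipes
IT F3	CCATACTTGCTTCGGCGGACC	107	I. tenuipes
IT R2	GCTCACAGATACAGGGTTGC	107	I. tenuipes
OS F1	AGCGTCATCTCAACCCTCGAG	200	O. sinensis
OS R2	TGATCCGAGGTCAACTGGAGG	200	O. sinensis
OS F3	GAACACCACAGCAGTTGCCT	117	O. sinensis
OS R3	GCTTCTTGACTGAGAGATGCC	117	O. sinensis
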