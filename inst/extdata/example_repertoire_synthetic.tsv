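sequence_id	cell_id	sequence	productive	locus	v_call	j_call	sequence_alignment	germline_alignment	fwr1	fwr1_aa	cdr1	cdr1_aa	fwr2	fwr2_aa	cdr2	cdr2_aa	fwr3	fwr3_aa	cdr3	cdr3_aa	fwr4	fwr4_aa	c_call
cellA1_contig_1	cellA1	CAGGTGCAGCTGGGATTCACCTTTTGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGATGGGGCCAAGGA	T	IGH	IGHV4-4*02	IGHJ4*02	CAGGTGCAGCTGGGATTCACCTTTTGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGATGGGGCCAAGGA	CAGGTGCAGCTGGGATTCACCTTTTGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGATGGGGCCAAGGA	CAGGTGCAGCTG	X	GGATTCACCTTT	X	TGGGTGCGACAG	X	ATCTCATACGAT	X	AGAGTCACCATT	X	GCGAGAGATACGTCGGGA	X	TGGGGCCAAGGA	X	IGHM
cellA1_contig_2	cellA1	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	T	IGK	IGKV1D-39*01	IGKJ1*01	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATG	X	CAGAGCATTAGC	X	TGGTATCAGCAG	X	GCTGCGTCC	X	GGGGTCCCATCA	X	CAACAGAGTTAC	X	TTCGGCGGAGGG	X	
cellA2_contig_1	cellA2	CAGGTGCAGCTGGGATTCACCTTTTGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGTTGGGGCCAAGGA	T	IGH	IGHV4-4*02	IGHJ4*02	CAGGTGCAGCTGGGATTCACCTTTTGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGTTGGGGCCAAGGA	CAGGTGCAGCTGGGATTCACCTTTTGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGATGGGGCCAAGGA	CAGGTGCAGCTG	X	GGATTCACCTTT	X	TGGGTGCGACAG	X	ATCTCATACGAT	X	AGAGTCACCATT	X	GCGAGAGATACGTCGGGT	X	TGGGGCCAAGGA	X	IGHG1
cellA2_contig_2	cellA2	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	T	IGK	IGKV1D-39*01	IGKJ1*01	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATG	X	CAGAGCATTAGC	X	TGGTATCAGCAG	X	GCTGCGTCC	X	GGGGTCCCATCA	X	CAACAGAGTTAC	X	TTCGGCGGAGGG	X	
cellA3_contig_1	cellA3	CAGGTGCAGCTGGGATTCACCTTATGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGTTGGGGCCAAGGA	T	IGH	IGHV4-4*02	IGHJ4*02	CAGGTGCAGCTGGGATTCACCTTATGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGTTGGGGCCAAGGA	CAGGTGCAGCTGGGATTCACCTTTTGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGATGGGGCCAAGGA	CAGGTGCAGCTG	X	GGATTCACCTTA	X	TGGGTGCGACAG	X	ATCTCATACGAT	X	AGAGTCACCATT	X	GCGAGAGATACGTCGGGT	X	TGGGGCCAAGGA	X	IGHG1
cellA3_contig_2	cellA3	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	T	IGK	IGKV1D-39*01	IGKJ1*01	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATG	X	CAGAGCATTAGC	X	TGGTATCAGCAG	X	GCTGCGTCC	X	GGGGTCCCATCA	X	CAACAGAGTTAC	X	TTCGGCGGAGGG	X	
cellA4_contig_1	cellA4	CAGGTGCAGCTGGGATTCACCTTATGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGTTTGGGGCCAAGGA	T	IGH	IGHV4-4*02	IGHJ4*02	CAGGTGCAGCTGGGATTCACCTTATGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGTTTGGGGCCAAGGA	CAGGTGCAGCTGGGATTCACCTTTTGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGATGGGGCCAAGGA	CAGGTGCAGCTG	X	GGATTCACCTTA	X	TGGGTGCGACAG	X	ATCTCATACGAT	X	AGAGTCACCATT	X	GCGAGAGATACGTCGGTT	X	TGGGGCCAAGGA	X	IGHA1
cellA4_contig_2	cellA4	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	T	IGK	IGKV1D-39*01	IGKJ1*01	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATG	X	CAGAGCATTAGC	X	TGGTATCAGCAG	X	GCTGCGTCC	X	GGGGTCCCATCA	X	CAACAGAGTTAC	X	TTCGGCGGAGGG	X	
cellA5_contig_1	cellA5	CAGGTGCAGCTGGGATTCACCTTATGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGTTGGGGCCAAGGA	T	IGH	IGHV4-4*02	IGHJ4*02	CAGGTGCAGCTGGGATTCACCTTATGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGTTGGGGCCAAGGA	CAGGTGCAGCTGGGATTCACCTTTTGGGTGCGACAGATCTCATACGATAGAGTCACCATTGCGAGAGATACGTCGGGATGGGGCCAAGGA	CAGGTGCAGCTG	X	GGATTCACCTTA	X	TGGGTGCGACAG	X	ATCTCATACGAT	X	AGAGTCACCATT	X	GCGAGAGATACGTCGGGT	X	TGGGGCCAAGGA	X	IGHG2
cellA5_contig_2	cellA5	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	T	IGK	IGKV1D-39*01	IGKJ1*01	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATGCAGAGCATTAGCTGGTATCAGCAGGCTGCGTCCGGGGTCCCATCACAACAGAGTTACTTCGGCGGAGGG	GACATCCAGATG	X	CAGAGCATTAGC	X	TGGTATCAGCAG	X	GCTGCGTCC	X	GGGGTCCCATCA	X	CAACAGAGTTAC	X	TTCGGCGGAGGG	X	
cellB1_contig_1	cellB1	CAGGTGCAGCTGGGATTCACCGTCTGGGTGCGACAGATTAGTGGTAGTAGAGTCACCATTGCGAAAGATCTATTTTGGGGCCAAGGA	T	IGH	IGHV3-23*01	IGHJ6*02	CAGGTGCAGCTGGGATTCACCGTCTGGGTGCGACAGATTAGTGGTAGTAGAGTCACCATTGCGAAAGATCTATTTTGGGGCCAAGGA	CAGGTGCAGCTGGGATTCACCGTCTGGGTGCGACAGATTAGTGGTAGTAGAGTCACCATTGCGAAAGATCTATTTTGGGGCCAAGGA	CAGGTGCAGCTG	X	GGATTCACCGTC	X	TGGGTGCGACAG	X	ATTAGTGGTAGT	X	AGAGTCACCATT	X	GCGAAAGATCTATTT	X	TGGGGCCAAGGA	X	IGHM
cellB1_contig_2	cellB1	GACATCCAGATGAGCTCCGACGTTTGGTATCAGCAGGAGGTCAGTGGGGTCCCATCAAGCTCATATACATTCGGCGGAGGG	T	IGL	IGLV2-14*01	IGLJ3*02	GACATCCAGATGAGCTCCGACGTTTGGTATCAGCAGGAGGTCAGTGGGGTCCCATCAAGCTCATATACATTCGGCGGAGGG	GACATCCAGATGAGCTCCGACGTTTGGTATCAGCAGGAGGTCAGTGGGGTCCCATCAAGCTCATATACATTCGGCGGAGGG	GACATCCAGATG	X	AGCTCCGACGTT	X	TGGTATCAGCAG	X	GAGGTCAGT	X	GGGGTCCCATCA	X	AGCTCATATACA	X	TTCGGCGGAGGG	X	
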