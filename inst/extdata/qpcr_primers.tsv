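gene	fw	rv	amplicon_bp	r_squared	efficiency	ta_celsius	conc_um
CBDAS-RTqPCR	GCAATACACACTTACTTCTCTTCAGTTTTC	ACGTAGTCTAACTTATCTTGAAAGCAC	241	0.99	1.04	61.5	0.075
THCAS-RTqPCR	AAAACTTCCTTAAATGCTTCTCAA	TAAAATAGTTGCTTGGATATGGGAGTT	198	0.94	0.8	58	0.175
CBCAS-RTqPCR	GCTCACGACTCACTTCAGAACTAG	GTAGAAGATGGTTGTATCAATCCAGCTC	198	0.98	1.01	62	0.1
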