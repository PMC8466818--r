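gene	fw	rv	amplicon_bp	note
CBCAS-cds	TGAAGAAAAATGAATTGCTCAACATTC	ACATAGTATGGGTAGATAATTAATGATGAC	1666	diagnostic-SNP-anchored pair
THCAS-cds	ATGAATTGCTCAGCATTTTCCTT	ATGATGATGCGGTGGAAGA	1635	stop codon immediately after the reverse primer
CBDAS-cds	ATGAAGTGCTCAACATTCTCCTT	TTAATGACGATGCCGTGGAA	1635	primers sit exactly on start and stop
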