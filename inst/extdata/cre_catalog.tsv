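name	consensus	category
G-box	CACGTG	nitrogen_status
GATA-box	HGATAR	nitrogen_status
MYB	TAACTG	nitrogen_status
MYC	CAATTG	nitrogen_status
ABRE	ACGTGGC	phytohormone
as-1	TGACGTCA	phytohormone
CGTCA-motif	CGTCA	phytohormone
TGACG-motif	TGACG	phytohormone
ERE	ATTTCAAA	phytohormone
TCA-element	CCATCTTTTT	phytohormone
TATA-box	TATAWA	core
CAAT-box	CCAAT	core
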