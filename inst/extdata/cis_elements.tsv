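element	pattern
G-box	CACGTG
Box4	ATTAAT
ABRE	ACGTGGC
TCA-element	CCATCTTTTT
MBS	CAACTG
HSE	AGAAAATTCG
TC-rich_repeats	ATTTTCTTCA
circadian	CAAAGATATC
Skn-1_motif	GTCAT
W-box	TTGACC
P-box	CCTTTTG
GAG-motif	AGAGAGT
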