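sample_id	cd8_tumour_density	cd8_stroma_density
S01	180	70
S02	220	90
S03	160	50
S04	250	110
S05	40	200
S06	55	240
S07	30	170
S08	8	6
S09	5	4
S10	3	2
S11	10	7
S12	0	0
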