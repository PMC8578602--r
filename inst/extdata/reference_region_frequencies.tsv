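family	metric	mir	nbr	ratio_printed	ratio_digits
BAR	pct_kac_per_k	20.5	9.8	2.1	1
PX	pct_kac_per_k	26.3	9.3	2.8	1
C2	pct_kac_per_k	22.9	10.5	2.2	1
EHD	pct_kac_per_k	28.9	27.8	1.0	1
Average	pct_kac_per_k	22.8	11.3	2.0	1
EHD	pct_kac	5.85	1.84	3.18	2
Average	pct_kac	3.30	0.71	4.65	2
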