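genotype	rate_per_day	rate_sd	abs_error_pct_2nd	abs_error_pct_3rd	abs_error_pct_avg	rel_error_pct_2nd	rel_error_pct_3rd	rel_error_pct_avg	survival50_weeks
Xpg-/-	1621	150	21.6	3.9	12.7	29.9	6.0	17.5	18.2
Ercc1d/-	2315	163	9.7	1.7	5.7	16.0	2.2	9.1	21.8
Ercc1-/-	4978	372	19.8	13.1	16.4	40.6	21.1	30.1	8.0
Wildtype	62	7.0	NA	NA	3.6	NA	NA	NA	120
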