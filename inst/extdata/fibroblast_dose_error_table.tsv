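uv_dose_J_m2	tbls_per_100kb	tbls_total	abs_error_pct	experimental_sem_pct	abs_error_sems	rel_error_pct	rel_error_sems
1	0.55	17600	1.18	5.61	0.21	7.90	1.41
2	1.10	35200	6.12	6.11	1.00	29.6	4.85
3	1.65	52800	0.94	9.39	0.10	2.76	0.29
4	2.20	70400	7.05	9.06	0.78	14.7	1.63
5	2.75	88000	12.0	7.86	1.53	20.7	2.64
6	3.30	105600	15.0	7.12	2.10	23.0	3.23
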