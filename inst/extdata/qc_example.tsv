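sample_id	freemix	duplication_rate	base_frac_A	base_frac_T	base_frac_G	base_frac_C
S001	0.001	0.05	0.295	0.295	0.205	0.205
S002	0.029	0.08	0.300	0.290	0.204	0.206
S003	0.030	0.04	0.296	0.294	0.206	0.204
S004	0.120	0.25	0.320	0.280	0.210	0.190
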