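label	expt	hf_el	hf_scod	diff
water	-6.31	-6.3±0.1	-6.5±0.1	0.2
methanol	-5.10	-4.7±0.4	-4.8±0.3	0.1
ethanol	-5.05	-3.5±0.5	-3.7±0.5	0.2
methanethiol	-1.24	-2.8±0.4	-3.1±0.4	0.3
acetamide	-9.68	-2.8±2.2	-2.7±2.2	0.0
tetrahydrofuran	-3.47	-2.6±0.3	-2.8±0.3	0.3
benzene	-0.86	-1.1±0.7	-1.6±0.7	0.5
phenol	-6.61	-9.9±1.2	-10.2±1.0	0.3
aniline	-5.49	-7.2±1.2	-7.8±1.2	0.6
ethane	1.83	2.2±0.2	1.9±0.2	0.3
hexane	2.48	2.6±0.6	2.1±0.6	0.5
cyclohexane	1.23	1.9±0.3	1.5±0.3	0.4
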