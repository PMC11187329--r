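stage	lipid_trait	target	f_stat	n_snps	beta	ci_low	ci_high	se	or_value	or_ci_low	or_ci_high	p
control	LDL	ANGPTL3	133.2343	3	0.240	-0.014	0.495	0.130	1.272	0.986	1.641	0.064
control	LDL	APOB	220.249859	19	0.217	0.101	0.334	0.060	1.243	1.106	1.397	<0.001
control	LDL	HMGCR	151.0792208	7	0.368	0.215	0.520	0.078	1.444	1.240	1.682	2.18E-06
control	LDL	LDLR	117.1812478	10	0.599	0.452	0.746	0.075	1.820	1.571	2.108	1.38E-15
control	LDL	NPC1L1	94.5278694	3	0.504	0.183	0.825	0.164	1.655	1.201	2.281	0.002
control	LDL	PCSK9	130.3062592	10	0.421	0.265	0.576	0.079	1.523	1.303	1.779	1.18E-07
control	LDL	PPARA	NA	0	NA	NA	NA	NA	NA	NA	NA	NA
control	LDL	LPL	NA	0	NA	NA	NA	NA	NA	NA	NA	NA
control	TG	ANGPTL3	209.4852653	3	0.240	-0.014	0.495	0.130	1.272	0.986	1.641	0.064
control	TG	APOC3	298.7056209	10	0.217	0.108	0.325	0.055	1.242	1.115	1.384	8.74E-05
control	TG	LPL	200.0503049	22	0.428	0.336	0.519	0.047	1.534	1.399	1.681	6.56E-20
control	TG	LDLR	NA	0	NA	NA	NA	NA	NA	NA	NA	NA
control	TG	PPARA	NA	0	NA	NA	NA	NA	NA	NA	NA	NA
disease	LDL	HMGCR	NA	7	-0.200	-0.896	0.497	0.355	0.819	0.408	1.644	0.574
disease	LDL	PCSK9	NA	12	0.578	0.122	1.034	0.233	1.782	1.129	2.812	0.013
disease	LDL	NPC1L1	NA	3	-0.651	-2.020	0.718	0.699	0.522	0.133	2.051	0.352
disease	LDL	APOB	NA	20	-0.324	-0.767	0.118	0.226	0.723	0.464	1.126	0.151
disease	LDL	LDLR	NA	14	0.458	0.069	0.847	0.199	1.581	1.071	2.334	0.021
disease	TG	APOC3	NA	10	0.382	-0.049	0.813	0.220	1.465	0.952	2.255	0.083
disease	TG	LPL	NA	24	0.475	0.117	0.832	0.182	1.607	1.124	2.299	0.009
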