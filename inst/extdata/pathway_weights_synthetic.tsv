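gene	EGFR	TGFb	JAK.STAT	Hypoxia	PI3K	MAPK	p53
PWG.001	3.144	0	0	0	0	0	0
PWG.002	1.402	0	0	0	0	0	0
PWG.003	1.653	0.237	-0.525	0	0	0	0
PWG.004	1.794	0	0	0.127	0	0	0
PWG.005	1.515	0	0.487	0	0	0	0
PWG.006	1.526	0	0	-0.627	0	0	0
PWG.007	2.374	0	0	0	0	0	0
PWG.008	1.942	0	0	0	0	0.227	0
PWG.009	0	2.234	0	0	0	0	0
PWG.010	0	1.553	0	0	0	0	-0.117
PWG.011	0	1.846	0	0	0	0	0
PWG.012	0	1.998	0	0	0	0	0
PWG.013	0	2.494	0	0	0	0	0
PWG.014	0	2.42	0	0	0	0	0
PWG.015	0	2.353	0	0	0	-0.078	0
PWG.016	1.087	2.653	0	0	0	0	0
PWG.017	0	0	1.565	0	0	0	0.458
PWG.018	0	0	2.359	0	0	0	0
PWG.019	0	0	2.055	0	0	0	0
PWG.020	0.13	0	1.961	0	0	0	0
PWG.021	0	0	1.79	0	0	0	0
PWG.022	0	0	1.719	0	0	0.315	0
PWG.023	0	0	2.499	0	0	0	0
PWG.024	0	0	1.447	0	0.063	0	0
PWG.025	0	0	0	1.804	0	0	0
PWG.026	0	0	0	1.799	0	0	0
PWG.027	0	0	0	2.675	0	0	0
PWG.028	0.758	0	0	2.296	0.232	0	0
PWG.029	0	0	0	2.05	0	0	0
PWG.030	0	0	0	2.466	0	0	0
PWG.031	0	0	0	1.869	0	0	0
PWG.032	0	-0.11	0	1.996	0	0	0
PWG.033	0	0	0	0	1.55	0	0
PWG.034	0.913	0	0	0	2.038	0	0
PWG.035	0	0	0	0	2.08	0	0
PWG.036	0	0	0	0	2.272	0	0
PWG.037	0	0	0	0	2.352	0	0
PWG.038	0	0	0	0	2.159	0	-0.058
PWG.039	0	0	0	0	2.555	0	0
PWG.040	0	0	-0.28	0	2.385	0	0
PWG.041	0	0	0	0	0	2.92	0
PWG.042	0	0	0	0	0	2.651	0
PWG.043	0	0	0	0	0	1.584	0
PWG.044	0	0.301	0	0	0	2.418	0.444
PWG.045	0	0	0	0	0	2.371	0
PWG.046	0	0	-0.114	0	0	2.441	0
PWG.047	0	0	0	0	0	2.51	0
PWG.048	0	0	0	0	0	2.211	0
PWG.049	0	0	0	0	0	0	1.998
PWG.050	0	0	0	0	0	0	3.012
PWG.051	0	0	0	0.066	0.013	0.247	1.732
PWG.052	0	0	0	0.192	0	0	2.716
PWG.053	0	-0.393	0	0	0	0	2.321
PWG.054	0	0	0	0	0	0	1.298
PWG.055	0	0	0	0	0.574	0	1.68
PWG.056	0	0	0	0	0	0	2.283
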