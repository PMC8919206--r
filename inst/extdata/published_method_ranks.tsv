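condition	gene	genorm_stability	genorm_rank	normfinder_stability	normfinder_rank	bestkeeper_stability	bestkeeper_rank	deltact_stability	deltact_rank
embryonic	GAPDH	0.218	4	0.043	1	0.421	6	0.73	1
embryonic	EF1A	0.129	1	0.433	5	0.294	3	0.774	3
embryonic	ACT5C	0.309	6	0.167	2	0.481	7	0.773	2
embryonic	NADH	0.129	1	0.51	7	0.326	4	0.827	6
embryonic	RPS23	0.177	3	0.503	6	0.206	2	0.797	5
embryonic	HSP67	0.275	5	0.352	3	0.378	5	0.78	4
embryonic	RPL5	0.41	7	1.074	10	0.144	1	1.18	10
embryonic	TBLg2	0.604	9	0.365	4	0.896	9	0.938	7
embryonic	TBLb1	0.513	8	0.844	9	0.677	8	1.127	9
embryonic	HSP83	0.695	10	0.727	8	1.051	10	1.079	8
embryonic	TATA	0.811	11	1.158	11	1.357	11	1.376	11
embryonic	18S	1.055	12	2.205	12	1.982	12	2.273	12
sexual	EF1A	0.531	1	0.682	4	1.402	2	1.524	2
sexual	ACT5C	0.678	3	0.181	1	1.803	7	1.469	1
sexual	TBLb1	0.531	1	0.626	3	1.573	5	1.554	3
sexual	TBLg2	0.788	4	0.465	2	1.742	6	1.565	4
sexual	RPL5	0.876	5	1.245	8	1.507	3	1.812	5
sexual	RPS23	1.136	7	1.656	10	0.764	1	2.127	10
sexual	NADH	1.26	8	1.168	6	1.518	4	1.902	8
sexual	TATA	1.001	6	1.221	7	1.936	8	1.885	7
sexual	GAPDH	1.365	9	1.083	5	2.476	10	1.859	6
sexual	HSP83	1.451	10	1.318	9	2.723	11	1.994	9
sexual	18S	1.757	11	3.048	11	2.464	9	3.3	11
sexual	HSP67	2.035	12	3.206	12	3.661	12	3.424	12
worker	TATA	0.614	5	0.244	2	0.601	2	1.01	1
worker	GAPDH	0.484	3	0.235	1	0.753	4	1.072	2
worker	NADH	0.423	1	0.642	5	1.02	8	1.111	3
worker	RPS23	0.693	7	0.245	3	0.379	1	1.164	6
worker	HSP83	0.423	1	0.704	7	0.994	6	1.163	5
worker	EF1A	0.744	8	0.631	4	1.032	9	1.15	4
worker	TBLg2	0.656	6	0.604	6	0.892	5	1.253	8
worker	HSP67	0.568	4	0.793	8	1.006	7	1.18	7
worker	ACT5C	0.982	11	0.96	10	0.707	3	1.527	10
worker	TBLb1	0.979	9	0.941	9	1.252	10	1.305	9
worker	RPL5	0.894	10	1.329	11	1.315	11	1.597	11
worker	18S	1.437	12	3.657	12	1.883	12	3.71	12
adult	EF1A	0.415	4	0.132	1	1.163	7	0.824	1
adult	ACT5C	0.123	1	0.354	3	1.086	6	0.873	2
adult	NADH	0.123	1	0.508	5	1.071	5	0.932	5
adult	TBLg2	0.272	3	0.515	6	0.837	2	0.919	4
adult	HSP67	0.462	5	0.38	4	0.952	3	0.888	3
adult	TBLb1	0.559	6	0.351	2	1.516	9	0.939	6
adult	RPS23	0.664	7	1.115	10	0.502	1	1.282	10
adult	RPL5	0.723	8	1.045	9	0.957	4	1.25	9
adult	GAPDH	0.805	9	0.898	7	1.441	8	1.197	7
adult	HSP83	0.894	10	0.9	8	1.920	10	1.215	8
adult	TATA	1.008	11	1.402	11	1.929	11	1.572	11
adult	18S	1.142	12	1.692	12	2.381	12	1.815	12
tissues	HSP67	0.568	3	0.418	1	0.768	1	1.012	1
tissues	RPL5	0.506	1	0.718	5	0.823	2	1.133	4
tissues	RPS23	0.506	1	0.624	3	0.956	5	1.084	3
tissues	NADH	0.687	5	0.460	2	0.827	3	1.074	2
tissues	TBLb1	0.627	4	0.731	6	1.063	8	1.145	5
tissues	TBLg2	0.918	8	0.708	4	1.069	9	1.218	6
tissues	EF1A	0.759	6	0.980	9	0.856	4	1.307	8
tissues	HSP83	0.828	7	0.809	7	0.957	6	1.234	7
tissues	GAPDH	1.072	10	0.975	8	1.013	7	1.385	9
tissues	ACT5C	1.132	11	1.164	10	1.326	10	1.487	10
tissues	TATA	0.996	9	1.213	11	1.559	11	1.488	11
tissues	18S	1.318	12	2.118	12	1.831	12	2.249	12
injection	EF1A	0.249	1	0.125	1	0.907	3	0.844	1
injection	TBLg2	0.249	1	0.177	2	0.767	2	0.887	2
injection	HSP67	0.38	3	0.347	3	0.944	5	0.934	4
injection	ACT5C	0.429	4	0.425	5	1.201	9	0.911	3
injection	TBLb1	0.457	5	0.353	4	1.136	8	0.941	5
injection	18S	1.053	11	1.492	11	0.588	1	1.721	11
injection	RPL5	0.521	6	0.674	6	1.047	7	1.013	6
injection	RPS23	0.719	9	0.968	9	0.908	4	1.242	9
injection	TATA	0.592	7	0.947	8	1.527	12	1.181	7
injection	HSP83	0.654	8	0.872	7	1.393	11	1.186	8
injection	GAPDH	0.909	10	1.352	10	1.346	10	1.589	10
injection	NADH	1.197	12	1.783	12	1.042	6	1.918	12
starvation	TBLg2	0.264	1	0.129	1	1.676	3	1.144	1
starvation	HSP67	0.264	1	0.485	4	1.495	1	1.219	3
starvation	RPL5	0.647	5	0.171	2	2.023	9	1.183	2
starvation	ACT5C	0.562	4	0.624	5	1.760	4	1.243	4
starvation	TBLb1	0.486	3	0.768	6	1.760	4	1.307	6
starvation	RPS23	0.914	9	0.924	7	1.502	2	1.479	7
starvation	HSP83	0.696	6	0.306	3	2.037	10	1.249	5
starvation	EF1A	0.790	7	1.250	8	1.926	7	1.556	8
starvation	TATA	0.857	8	1.304	9	1.899	6	1.620	9
starvation	18S	1.183	10	2.124	10	1.974	8	2.398	10
starvation	GAPDH	1.438	11	2.209	11	2.436	11	2.402	11
starvation	NADH	1.602	12	2.242	12	2.714	12	2.422	12
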