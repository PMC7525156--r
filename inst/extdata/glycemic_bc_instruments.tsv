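trait	dataset	gene	rsid	chrom	pos	ref	alt	eaf	exp_beta	exp_pval	out_or	out_ci_low	out_ci_high	out_pval
FG	OncoArray	PROX1	rs340874	1	214159256	T	C	0.562	0.020	1.69e-13	0.982	0.969	0.994	0.004
FG	OncoArray	G6PC2	rs560887	2	169763148	T	C	0.674	0.067	8.08e-92	0.994	0.980	1.008	0.389
FG	OncoArray	GCKR	rs780094	2	27741237	T	C	0.606	0.031	3.06e-26	1.012	0.999	1.024	0.070
FG	OncoArray	ADCY5	rs11708067	3	123065778	G	A	0.774	0.027	5.01e-16	1.004	0.989	1.018	0.644
FG	OncoArray	SLC2A2	rs11924648	3	170717996	G	A	0.863	0.029	1.74e-11	0.985	0.968	1.003	0.104
FG	OncoArray	PCSK1	rs7713317	5	95716722	G	A	0.695	0.023	6.50e-14	0.995	0.981	1.009	0.476
FG	OncoArray	AC006045.3	rs1558318	7	15065612	T	A	0.545	-0.028	2.93e-20	1.003	0.991	1.016	0.595
FG	OncoArray	GCK	rs4607517	7	44235668	G	A	0.195	0.058	2.66e-46	1.000	0.982	1.017	0.959
FG	OncoArray	SLC30A8	rs3802177	8	118185025	G	A	0.239	-0.034	1.12e-27	0.984	0.971	0.997	0.016
FG	OncoArray	PPP1R3B	rs983309	8	9177732	T	G	0.903	-0.032	4.85e-13	1.020	1.000	1.040	0.050
FG	OncoArray	GLIS3	rs10814916	9	4293150	C	A	0.434	-0.019	7.61e-10	1.006	0.993	1.019	0.372
FG	OncoArray	CDKN2B-AS1	rs2383208	9	22132076	G	A	0.792	0.026	1.19e-13	0.986	0.970	1.001	0.070
FG	OncoArray	ADRA2A	rs11195502	10	113039667	T	C	0.925	0.035	7.41e-12	1.020	0.998	1.042	0.080
FG	OncoArray	TMEM258	rs102275	11	61557803	T	C	0.351	-0.019	1.01e-09	0.993	0.981	1.006	0.292
FG	OncoArray	MTNR1B	rs10830963	11	92708710	G	C	0.700	-0.074	1.36e-98	0.992	0.978	1.007	0.284
FG	OncoArray	CTD-2210P24.6	rs6485644	11	45855998	T	C	0.531	0.019	1.39e-10	0.991	0.979	1.003	0.154
FG	OncoArray	MADD	rs7944584	11	47336320	T	A	0.712	0.024	2.20e-12	1.031	1.016	1.045	0.001
FG	OncoArray	PDX1	rs11619319	13	28487599	G	A	0.788	-0.021	9.26e-10	1.003	0.989	1.018	0.662
FG	OncoArray	VPS13C/C2CD4A/B	rs4502156	15	62383155	T	C	0.420	-0.023	3.07e-15	1.016	1.003	1.030	0.014
FG	ATLAS-CGEMS	PROX1	rs340874	1	214159255	T	C	0.562	0.020	1.69e-13	0.991	0.819	1.198	0.913
FG	ATLAS-CGEMS	G6PC2	rs560887	2	169763147	T	C	0.674	0.067	8.08e-92	1.006	0.846	1.196	0.745
FG	ATLAS-CGEMS	GCKR	rs780094	2	27741236	T	C	0.606	0.031	3.06e-26	0.994	0.828	1.193	0.983
FG	ATLAS-CGEMS	RNU1-70P	rs11709140	3	170694496	T	C	0.137	-0.026	1.90e-09	0.937	0.769	1.140	0.435
FG	ATLAS-CGEMS	ADCY5	rs2877716	3	123094450	T	C	0.752	0.023	7.27e-11	1.029	0.865	1.225	0.919
FG	ATLAS-CGEMS	PCSK1	rs4869272	5	95539447	T	C	0.323	-0.022	1.64e-13	1.070	0.900	1.272	0.721
FG	ATLAS-CGEMS	AC006045.3	rs2191348	7	15064254	T	G	0.482	-0.026	2.56e-18	1.000	0.827	1.208	1.000
FG	ATLAS-CGEMS	GCK	rs4607517	7	44235667	G	A	0.195	0.058	2.66e-46	0.918	0.762	1.105	0.207
FG	ATLAS-CGEMS	SLC30A8	rs13266634	8	118184782	T	C	0.761	0.030	6.72e-21	1.015	0.852	1.208	0.467
FG	ATLAS-CGEMS	PPP1R3B	rs983309	8	9177731	T	G	0.903	-0.032	4.85e-13	0.971	0.783	1.203	0.937
FG	ATLAS-CGEMS	GLIS3	rs10814916	9	4293149	C	A	0.434	-0.019	7.61e-10	0.999	0.823	1.213	0.999
FG	ATLAS-CGEMS	CDKN2B-AS1	rs2383208	9	22132075	G	A	0.792	0.026	1.19e-13	1.065	0.886	1.278	0.039
FG	ATLAS-CGEMS	BTBD7P2	rs4258313	10	113032397	T	G	0.914	0.037	1.82e-11	1.027	0.827	1.275	0.625
FG	ATLAS-CGEMS	TMEM258	rs102275	11	61557802	T	C	0.351	-0.019	1.01e-09	1.029	0.865	1.225	0.768
FG	ATLAS-CGEMS	CRY2	rs11607883	11	45839708	G	A	0.469	-0.018	1.86e-10	1.006	0.829	1.219	0.967
FG	ATLAS-CGEMS	ACP2	rs11988	11	47261259	G	A	0.372	-0.021	5.07e-12	0.916	0.765	1.095	0.412
FG	ATLAS-CGEMS	MTNR1B	rs1387153	11	92673827	T	C	0.728	-0.054	1.27e-58	0.954	0.803	1.134	0.619
FG	ATLAS-CGEMS	PDX1-AS1	rs2293941	13	28491197	G	A	0.212	0.021	1.42e-09	1.101	0.923	1.312	0.470
FG	ATLAS-CGEMS	NPM1P47	rs7172432	15	62396388	G	A	0.580	0.023	3.15e-11	0.888	0.739	1.068	0.448
FG	ATLAS-GEEA	PROX1-AS1	rs1431985	1	214148245	G	A	0.327	-0.019	1.15e-09	0.989	0.964	1.016	0.427
FG	ATLAS-GEEA	SNX17	rs1528533	2	27595755	G	C	0.458	0.018	5.29e-09	0.988	0.962	1.016	0.406
FG	ATLAS-GEEA	ABCB11	rs494874	2	169789305	T	C	0.628	0.053	1.82e-68	1.004	0.976	1.034	0.771
FG	ATLAS-GEEA	SLC2A2	rs10513686	3	170725541	G	A	0.142	-0.027	3.73e-10	1.003	0.968	1.039	0.878
FG	ATLAS-GEEA	AC006045.3	rs10487796	7	15063429	T	A	0.525	-0.027	8.54e-20	0.980	0.954	1.007	0.140
FG	ATLAS-GEEA	BTBD7P2	rs10509938	10	113028616	T	C	0.920	0.035	3.18e-11	1.016	0.961	1.073	0.580
FG	ATLAS-GEEA	MADD	rs10501320	11	47293798	G	C	0.292	-0.022	3.47e-08	1.004	0.975	1.034	0.808
FG	ATLAS-GEEA	MTNR1B	rs1387153	11	92673827	T	C	0.728	-0.054	1.27e-58	1.020	0.987	1.054	0.230
FG	ATLAS-GEEA	FADS2	rs1535	11	61597971	G	A	0.659	0.019	2.75e-09	1.013	0.983	1.044	0.405
FG	ATLAS-GEEAB	PROX1-AS1	rs1431985	1	214148245	G	A	0.327	-0.019	1.15e-09	0.990	0.964	1.016	0.441
FG	ATLAS-GEEAB	SNX17	rs1528533	2	27595755	G	C	0.458	0.018	5.29e-09	0.988	0.961	1.016	0.399
FG	ATLAS-GEEAB	ABCB11	rs494874	2	169789305	T	C	0.628	0.053	1.82e-68	1.004	0.975	1.033	0.801
FG	ATLAS-GEEAB	SLC2A2	rs10513686	3	170725541	G	A	0.142	-0.027	3.73e-10	1.001	0.966	1.038	0.941
FG	ATLAS-GEEAB	AC006045.3	rs10487796	7	15063429	T	A	0.525	-0.027	8.54e-20	0.980	0.954	1.007	0.146
FG	ATLAS-GEEAB	BTBD7P2	rs10509938	10	113028616	T	C	0.920	0.035	3.18e-11	1.014	0.959	1.072	0.624
FG	ATLAS-GEEAB	MADD	rs10501320	11	47293798	G	C	0.292	-0.022	3.47e-08	1.004	0.975	1.034	0.798
FG	ATLAS-GEEAB	MTNR1B	rs1387153	11	92673827	T	C	0.728	-0.054	1.27e-58	1.020	0.987	1.055	0.233
FG	ATLAS-GEEAB	FADS2	rs1535	11	61597971	G	A	0.659	0.019	2.75e-09	1.013	0.982	1.044	0.413
FI	OncoArray	COBLL1	rs10179126	2	165511794	G	C	0.605	0.021	3.78e-08	1.008	0.995	1.021	0.208
FI	OncoArray	GCKR	rs780093	2	27742603	T	C	0.606	0.021	8.48e-09	1.011	0.999	1.024	0.076
FI	OncoArray	ZNF12/AC073343.13	rs7798471	7	6744957	T	C	0.243	0.026	1.55e-08	0.997	0.984	1.011	0.680
FI	OncoArray	RP11-115J16.1	rs4240624	8	9184231	G	A	0.925	-0.038	1.10e-09	1.027	1.005	1.050	0.016
FI	ATLAS-CGEMS	GCKR	rs780094	2	27741236	T	C	0.606	0.021	1.00e-08	0.994	0.828	1.193	0.983
FI	ATLAS-CGEMS	ZNF12/AC073343.13	rs7798471	7	6744956	T	C	0.243	0.026	1.55e-08	1.063	0.895	1.263	0.708
FI	ATLAS-CGEMS	PPP1R3B	rs983309	8	9177731	T	G	0.903	-0.032	2.03e-09	0.971	0.783	1.203	0.937
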