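gene_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012
G00001	12.9161	16.1408	10.15	13.2937	17.8526	17.3126	15.481	12.0552	12.7296	18.5567	18.1476	17.9555
G00002	2.59413	5.49882	7.76818	7.64781	8.15278	9.67728	5.34411	8.43094	5.03401	11.0218	8.48405	6.86831
G00003	763.349	582.764	29.1519	1555.45	835.904	931.842	83.5258	512.162	801.4	150.265	385.23	1071.56
G00004	577.861	474.032	201.091	1015.99	487.882	498.834	233.463	538.951	611.41	288.605	308.827	516.6
G00005	8.70634	7.10986	31.5378	1.12562	157.143	10.1967	17.3371	41.5086	36.6738	8.58586	24.3177	38.3327
G00006	8.01933	8.39467	8.08466	2.39569	67.8119	18.3015	23.8741	19.9642	25.4267	4.90084	13.6324	29.6741
G00007	5.42011	5.7734	3.9854	4.6008	6.01122	6.18446	6.82955	3.18806	12.4453	8.11216	9.72674	25.7244
G00008	18.1061	17.2249	11.7805	9.09795	16.3098	17.6704	13.7554	14.7006	31.6889	20.4374	49.9523	35.4953
G00009	39.961	12.6436	21.3802	26.9465	25.9705	40.7578	28.9048	52.7888	45.9384	180.32	4.95224	9.88572
G00010	2595.89	2017.27	2286.63	3940.77	2196.31	3103.23	2621.16	3217.64	2796.14	6055.01	1189.29	1252.14
G00011	2543.38	5619.28	417.894	4968.27	2561.61	390.224	1847.79	1703.1	5856.41	5366.27	2799.06	2294.2
G00012	65.193	144.04	16.4535	122.751	124.331	5.14636	76.5625	28.6584	90.719	96.6476	77.2771	92.1087
G00013	37.9787	21.0697	26.7434	40.436	68.4608	67.9222	105.322	96.4221	30.154	16.7811	261.032	156.07
G00014	15.5034	10.0543	8.78054	5.04127	11.4155	17.1218	33.6338	29.7231	9.06615	3.65618	179.374	50.4642
G00015	17416.4	3805.11	4074.59	2350.2	6212.02	8424.03	381.697	3579.57	5572.67	2299.87	1549.09	12841.7
G00016	15058.2	2250.38	3587.79	2380.32	3335.25	3901.66	847.529	3289.18	4109.26	2476.66	1838.33	6076.71
G00017	4.41406	39.4112	11.3542	32.3925	109.457	317.556	2.16588	28.9458	4.48553	23.1139	76.8243	58.6587
G00018	28.2236	86.4346	35.3807	68.4193	182.451	495.107	6.16648	112.698	13.4082	62.3291	94.3473	122.058
G00019	6.2697	3.46988	10.2901	39.7491	6.44925	31.3315	19.1878	2.69889	19.3352	32.135	9.29626	16.9233
G00020	2.49034	0.88716	7.00809	46.0079	1.11768	25.6008	6.59735	0.662058	18.5033	14.1892	2.90137	12.6976
G00021	181.985	142.988	229.718	751.488	145.674	86.7907	1088.34	33.524	163.402	470.217	110.327	663.145
G00022	986.536	2131.02	607.493	3844.53	350.189	491.228	4558.99	239.862	801.64	1341.86	662.924	1974.88
G00023	14.9262	4.87328	6.17653	5.89785	6.10902	4.55276	1.79717	1.70826	5.64384	3.2407	4.58249	8.04437
G00024	612.282	52.7444	52.9293	162.523	94.2062	63.169	8.54566	6.0537	61.4289	13.1301	35.5986	92.1024
G00025	432.845	7.56472	30.3441	106.236	3.68944	128.186	186.077	21.3699	15.3295	5.86294	10.7458	567.105
G00026	1002.35	235.174	378.571	588.67	265.976	560.447	676.068	367.783	372.701	201.878	387.173	1205.32
G00027	138.254	329.584	178.298	46.368	57.6482	313.231	196.755	146.404	195.714	298.901	168.913	90.6249
G00028	468.269	663.072	2099.9	237.084	160.053	1828.66	695.497	728.818	3449.09	816.537	608.255	368.518
G00029	2.4968	4.39076	16.5696	20.2374	3.94089	7.86559	11.7883	3.65312	3.44416	3.63494	2.72578	6.10858
G00030	102.031	174.563	347.738	288.47	100.165	221.358	263.978	150.936	114.758	96.4843	96.0862	212.104
G00031	20.9519	15.6747	13.0963	5.90261	2.46846	5.1216	7.77101	10.6773	18.7879	4.08563	12.6774	3.18175
G00032	5060.62	6313.25	6560.21	3051.75	1909.6	2824.31	4272.67	8214.23	8941.79	1845.79	3559.79	2812.48
G00033	77.7696	149.752	141.692	69.6434	207.501	332.04	291.039	254.465	155.138	77.0733	70.1172	264.119
G00034	1.71437	8.18344	5.15366	5.69296	43.0498	93.4775	56.1527	35.3986	15.4762	3.23406	1.58385	47.225
G00035	18.5428	7.97788	14.2322	72.9211	51.3526	8.57537	29.2771	23.6907	134.994	10.6083	29.8352	62.8297
G00036	2.45539	2.64276	3.73825	10.5413	5.09052	3.55903	5.09484	3.47844	12.8367	2.74093	3.58549	7.34605
G00037	36.0299	108.894	35.0822	47.9501	99.0609	13.3049	9.72063	33.4564	31.2406	55.7839	25.4547	39.8706
G00038	149.237	1062.34	325.542	447.443	932.829	55.6404	27.2933	187.597	91.3407	420.558	61.5617	351.834
G00039	831.019	1964	11416.3	623.966	882.942	1594.08	826.979	935.788	659.395	1036.39	889.003	616.839
G00040	1888.14	4289.15	11281.8	1593.28	2822.78	4311.28	2270.59	3150.45	1700.01	2771.85	1598.31	2570.08
G00041	8.5733	15.6785	2.47166	11.9719	24.4903	19.3188	44.3697	72.2852	33.6498	0.641858	11.275	13.019
G00042	137.719	208.931	306.187	109.882	242.759	174.139	113.633	124.852	96.1906	261.592	165.312	117.974
G00043	129.586	744.926	136.078	498.484	281.091	399.504	603.577	493.412	1431.31	756.702	859.625	281.849
G00044	8.04407	20.5377	27.5299	28.7495	11.3344	94.9677	64.4038	11.9081	60.011	10.2273	22.3798	24.6248
G00045	1698.29	1433.8	2125.21	3960.93	4762.04	1694.65	5657.03	5351.71	2345.85	4725.84	2735.43	1395.58
G00046	631.754	338.951	838.144	410.411	742.969	569.165	528.081	90.4298	362.687	209.136	138.946	171.805
G00047	4.56911	4.29354	20.5349	10.6937	64.8126	42.8898	41.8185	6.62759	9.81555	33.3317	11.333	4.7726
G00048	15.5664	34.2199	23.7866	36.9897	39.8714	23.7516	27.04	53.4876	82.5095	41.18	18.5703	26.6689
G00049	54.6804	141.859	178.99	196.469	535.915	157.609	251.085	555.931	129.474	469.974	25.1059	176.24
G00050	1612.93	156.875	217.622	197.238	40.0821	320.949	58.5908	293.692	462.189	639.871	1339.73	149.32
G00051	5.99997	6.56787	10.1245	3.37025	19.4031	9.19283	3.58735	7.32328	4.49342	8.89584	3.82204	14.42
G00052	5433.72	60747.9	3610.04	2503.75	3392.16	70568.2	1343.66	1890.25	2480.11	175.674	5068.64	1431.54
G00053	20113.9	462.36	14048.3	3508.22	2318.65	364.48	1770.39	3202.76	653.992	20450.7	10519.8	3430.99
G00054	18542.8	1424.72	11050.7	1343.54	7799.19	3038.89	1214.23	375.061	4422.47	1279.69	6353.57	1262.69
G00055	276.198	235.411	432.69	100.758	137.078	293.09	567.594	50.1307	90.4589	680.821	260.093	170.538
G00056	892.749	5571.08	2395.59	452.845	612.472	4862.32	1518.79	2674.18	2153.91	8523.72	583.859	1187.79
G00057	36.1239	114.139	53.5742	80.0546	55.4835	84.9061	46.3411	77.9994	88.2662	69.1348	98.4671	63.5634
G00058	21.7403	14.9054	23.3573	53.7405	116.433	17.5214	15.6963	9.29546	123.385	13.8164	183.171	69.7525
G00059	25.2693	33.3967	19.335	15.9558	34.4894	17.2049	21.4931	40.8958	26.0259	8.6759	31.9826	9.46789
G00060	13.1882	4.56663	7.00561	15.7508	5.22818	9.79369	13.5549	30.6668	14.6205	15.6789	14.1256	6.18498
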