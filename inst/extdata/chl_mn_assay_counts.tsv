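chemical	dose_ug_ml	n_images	manual_total	manual_mn	manual_mn_pct	initial_total	initial_mn	initial_mn_pct	initial_star	individual_total	individual_mn	individual_mn_pct	batch_total	batch_mn	batch_mn_pct	viability_pct
Control	0	45	1555	11	0.71	1548	13	0.84		1549	16	1.03	1593	23	1.44	100
H2O2	3.75	55	1340	35	2.61	1352	155	11.46	***	1352	32	2.37	1352	25	1.85	71
H2O2	7.5	57	1292	68	5.26	1336	91	6.81	*	1297	72	5.55	1334	60	4.50	66
H2O2	15	43	1250	95	7.60	1262	93	7.37		1262	93	7.37	1262	93	7.37	84
H2O2	30	79	2040	189	9.26	2053	257	12.52	*	2055	197	9.59	2093	197	9.41	75
K2CrO4	1.2	50	1353	36	2.66	1354	30	2.22		1354	31	2.29	1348	32	2.37	78
K2CrO4	2.4	60	1436	91	6.34	1408	87	6.18		1408	89	6.32	1413	84	5.94	69
K2CrO4	4.9	66	1270	139	10.94	1280	98	7.66	*	1274	129	10.13	1299	118	9.08	56
MMC	0.0125	49	1919	62	3.23	1901	76	4.00		1896	68	3.59	1910	78	4.08	113
MMC	0.025	36	1661	69	4.15	1679	112	6.67	**	1676	72	4.30	1688	62	3.67	134
MMC	0.05	30	1465	199	13.58	1456	225	15.45		1456	198	13.60	1497	183	12.22	141
MMC	0.1	80	1203	472	39.24	1172	464	39.59		1172	455	38.82	1182	448	37.90	44
MMC	0.2	65	1684	326	19.36	1682	378	22.47		1688	319	18.90	1704	321	18.84	75
MMS	10	49	1658	76	4.58	1642	80	4.87		1639	68	4.15	1647	90	5.46	98
MMS	20	50	1147	106	9.24	1145	115	10.04		1143	116	10.15	1123	113	10.06	66
MMS	40	73	1347	250	18.56	1363	257	18.86		1359	239	17.59	1361	257	18.88	53
MMS	80	187	1155	50	4.33	1136	135	11.88	***	1136	52	4.58	1149	58	5.05	18
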