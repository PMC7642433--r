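gene_id	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10	S11	S12
CYT_01	1690	2035	1805	2150	1920	1690	2035	226	269	240	211	254
CYT_02	2240	1971	2374	2106	2509	2240	1971	297	263	314	280	246
CYT_03	2867	2560	2253	2714	2406	2867	2560	282	339	301	358	320
CYT_04	2707	3226	2880	2534	3053	2707	3226	360	317	382	338	403
CYT_05	3392	3008	3584	3200	2816	3392	3008	448	400	352	424	376
CYT_06	3098	3731	3309	3942	3520	3098	3731	414	493	440	387	466
CYT_07	1600	1408	1696	1504	1792	1600	1408	212	188	224	200	176
CYT_08	2150	1920	1690	2035	1805	2150	1920	211	254	226	269	240
CYT_09	2106	2509	2240	1971	2374	2106	2509	280	246	297	263	314
CYT_10	2714	2406	2867	2560	2253	2714	2406	358	320	282	339	301
AP_01	317	382	338	403	60	53	64	338	403	360	317	382
AP_02	400	352	424	376	75	67	59	424	376	448	400	352
AP_03	493	440	387	466	69	82	73	387	466	414	493	440
AP_04	188	224	200	176	35	31	37	200	176	212	188	224
AP_05	254	226	269	240	35	42	38	269	240	211	254	226
AP_06	246	297	263	314	47	41	50	263	314	280	246	297
AP_07	320	282	339	301	59	53	47	339	301	358	320	282
AP_08	403	360	317	382	56	67	60	317	382	338	403	360
TGFB_01	376	448	400	352	2544	2256	2688	400	352	424	376	448
TGFB_02	466	414	493	440	2323	2798	2482	493	440	387	466	414
TGFB_03	176	212	188	224	1200	1056	1272	188	224	200	176	212
TGFB_04	240	211	254	226	1613	1440	1267	254	226	269	240	211
TGFB_05	314	280	246	297	1579	1882	1680	246	297	263	314	280
TGFB_06	301	358	320	282	2035	1805	2150	320	282	339	301	358
TGFB_07	382	338	403	360	1901	2290	2030	403	360	317	382	338
TGFB_08	352	424	376	448	2400	2112	2544	376	448	400	352	424
DES_01	440	387	466	414	493	440	387	2798	2482	2957	2640	2323
DES_02	224	200	176	212	188	224	200	1056	1272	1128	1344	1200
DES_03	226	269	240	211	254	226	269	1440	1267	1526	1354	1613
DES_04	297	263	314	280	246	297	263	1882	1680	1478	1781	1579
DES_05	282	339	301	358	320	282	339	1805	2150	1920	1690	2035
DES_06	360	317	382	338	403	360	317	2290	2030	2419	2160	1901
DES_07	448	400	352	424	376	448	400	2112	2544	2256	2688	2400
DES_08	414	493	440	387	466	414	493	2640	2323	2798	2482	2957
ACTB	31800	28200	33600	30000	26400	31800	28200	33600	30000	26400	31800	28200
ACTG1	26400	31800	28200	33600	30000	26400	31800	28200	33600	30000	26400	31800
HSP90AB1	30000	26400	31800	28200	33600	30000	26400	31800	28200	33600	30000	26400
UBC	33600	30000	26400	31800	28200	33600	30000	26400	31800	28200	33600	30000
NOISE_01	338	403	360	317	382	338	403	360	317	382	338	403
NOISE_02	424	376	448	400	352	424	376	448	400	352	424	376
NOISE_03	387	466	414	493	440	387	466	414	493	440	387	466
NOISE_04	200	176	212	188	224	200	176	212	188	224	200	176
NOISE_05	269	240	211	254	226	269	240	211	254	226	269	240
NOISE_06	263	314	280	246	297	263	314	280	246	297	263	314
NOISE_07	339	301	358	320	282	339	301	358	320	282	339	301
NOISE_08	317	382	338	403	360	317	382	338	403	360	317	382
NOISE_09	400	352	424	376	448	400	352	424	376	448	400	352
NOISE_10	493	440	387	466	414	493	440	387	466	414	493	440
NOISE_11	188	224	200	176	212	188	224	200	176	212	188	224
NOISE_12	254	226	269	240	211	254	226	269	240	211	254	226
NOISE_13	246	297	263	314	280	246	297	263	314	280	246	297
NOISE_14	320	282	339	301	358	320	282	339	301	358	320	282
NOISE_15	403	360	317	382	338	403	360	317	382	338	403	360
NOISE_16	376	448	400	352	424	376	448	400	352	424	376	448
NOISE_17	466	414	493	440	387	466	414	493	440	387	466	414
NOISE_18	176	212	188	224	200	176	212	188	224	200	176	212
NOISE_19	240	211	254	226	269	240	211	254	226	269	240	211
NOISE_20	314	280	246	297	263	314	280	246	297	263	314	280
NOISE_21	839303	358	320	282	339	301	358	320	282	339	301	358
NOISE_22	1	338	403	360	317	382	338	403	360	317	382	338
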