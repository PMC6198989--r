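chrom	start	end	read_count	background_count
chr1	6560	7006	251	35
chr1	11322	11714	225	42
chr1	16706	17048	200	26
chr1	19849	20124	175	25
chr1	21735	22229	308	50
chr1	27290	27717	265	50
chr1	32694	33184	267	43
chr1	34598	34926	222	32
chr1	44195	44451	144	32
chr1	46536	46752	120	28
chr1	58548	58876	227	36
chr1	65266	65715	262	38
chr1	67476	67898	252	45
chr1	70466	70783	187	34
chr1	72083	72535	850	44
chr1	76366	76687	172	25
chr1	78146	78636	307	51
chr1	87720	88165	796	45
chr1	92950	93179	151	21
chr1	95098	95399	550	31
chr1	96427	96651	113	11
chr1	100397	100697	176	23
chr1	102237	102537	209	35
chr1	106260	106559	158	30
chr1	109593	110001	227	34
chr1	114238	114668	779	52
chr1	118656	119056	234	46
chr1	128626	129123	298	49
chr1	138990	139212	137	26
chr1	144522	144966	863	49
chr1	150764	151234	307	47
chr1	154843	155205	187	37
chr1	158570	158770	141	16
chr1	160392	160746	219	30
chr1	161991	162233	140	22
chr1	163371	163612	118	26
chr1	164902	165288	680	44
chr1	166871	167216	228	47
chr1	168813	169199	228	42
chr1	170651	171098	268	58
chr1	175684	176074	242	40
chr1	181179	181429	152	21
chr1	185242	185636	240	48
chr1	193082	193489	238	43
chr1	198460	198864	257	46
chr1	211118	211439	175	23
chr1	215179	215600	230	34
chr1	218105	218377	166	25
chr1	222924	223330	229	38
chr1	226864	227310	818	45
chr1	232004	232403	714	33
chr1	236322	236751	245	48
chr1	238743	239152	243	42
chr1	248147	248374	158	20
chr1	253209	253619	241	47
chr1	257747	258234	295	38
chr1	260269	260613	176	36
chr1	268914	269382	289	37
chr1	276889	277384	957	46
chr1	286888	287157	164	20
chr1	288662	289098	309	41
chr1	290416	290887	251	48
chr1	297214	297482	171	29
chr1	299450	299899	276	49
chr1	310573	310959	234	44
chr1	315377	315632	478	18
chr1	318664	318956	186	27
chr1	321554	321872	201	45
chr1	324209	324545	186	31
chr1	333092	333378	177	30
chr1	335008	335470	257	51
chr1	343655	343930	164	26
chr1	345551	345785	151	20
chr1	350642	351004	225	40
chr1	356135	356615	886	38
chr1	360965	361365	261	40
chr1	369195	369500	207	32
chr1	372293	372559	487	22
chr1	376787	377057	499	28
chr1	380721	381090	223	33
chr1	387531	387741	137	16
chr1	389123	389419	200	26
chr1	399876	400091	140	26
chr1	402277	402538	134	30
chr1	404674	405019	231	30
chr1	407222	407592	214	35
chr1	411696	412038	193	35
chr1	419071	419391	198	29
chr1	421617	422011	241	29
chr1	424442	424925	259	43
chr1	436500	436767	130	31
chr1	438156	438543	229	25
chr1	441732	442193	280	39
chr1	452112	452361	428	20
chr1	456655	456919	157	24
chr1	458937	459350	240	40
chr1	460749	461171	237	32
chr1	463385	463851	285	34
chr1	465772	466114	206	24
chr1	472331	472652	583	29
chr1	473975	474317	219	25
chr1	477821	478276	265	47
chr1	481216	481636	231	34
chr1	486877	487091	116	30
chr1	489798	490179	701	30
chr1	492680	492990	163	26
chr2	1095	1476	710	46
chr2	19766	20021	174	20
chr2	21428	21717	165	29
chr2	26934	27185	159	25
chr2	31108	31450	631	35
chr2	33102	33554	266	40
chr2	35274	35698	249	38
chr2	40474	40849	247	42
chr2	45017	45372	187	51
chr2	46578	46855	159	26
chr2	62802	63201	238	38
chr2	64954	65257	186	35
chr2	67262	67531	173	22
chr2	70608	70813	130	19
chr2	72281	72504	124	29
chr2	77645	78036	246	40
chr2	84041	84304	142	22
chr2	85376	85616	129	25
chr2	92896	93176	164	31
chr2	98256	98691	276	47
chr2	111984	112416	258	42
chr2	116369	116587	149	18
chr2	121813	122289	298	59
chr2	124020	124499	265	50
chr2	131158	131428	164	19
chr2	135075	135437	220	31
chr2	139130	139506	245	42
chr2	144511	144920	253	40
chr2	148830	149289	257	44
chr2	161733	162086	219	25
chr2	165111	165517	236	46
chr2	167560	167956	237	41
chr2	171338	171716	212	40
chr2	175164	175485	204	29
chr2	177543	177973	263	44
chr2	181597	182055	291	39
chr2	184898	185309	234	43
chr2	190167	190431	459	28
chr2	205999	206484	312	38
chr2	209772	210057	181	19
chr2	215770	216182	277	36
chr2	217917	218296	224	31
chr2	220529	220799	179	22
chr2	222537	222972	254	46
chr2	231113	231458	180	30
chr2	233721	234052	216	36
chr2	236322	236728	232	56
chr2	241886	242158	489	18
chr2	246352	246563	391	19
chr2	252857	253306	257	50
chr2	254505	254714	116	14
chr2	258816	259117	185	27
chr2	262408	262905	877	46
chr2	264594	264939	611	24
chr2	266827	267217	248	35
chr2	270822	271118	172	23
chr2	273290	273683	229	31
chr2	275922	276219	180	27
chr2	290052	290390	566	38
chr2	298374	298692	196	35
chr2	302876	303288	246	33
chr2	304716	304946	409	30
chr2	306348	306747	229	40
chr2	317686	318149	294	44
chr2	319964	320197	148	22
chr2	324432	324715	158	38
chr2	326576	326975	254	33
chr2	330605	330903	170	33
chr2	332492	332700	369	16
chr2	334590	334844	154	22
chr2	341308	341724	720	51
chr2	345535	345802	173	29
chr2	347586	347881	507	28
chr2	353349	353719	212	37
chr2	362668	362954	171	37
chr2	365016	365414	238	36
chr2	369752	370070	200	33
chr2	376939	377273	644	27
chr2	380243	380681	278	27
chr2	382122	382334	134	20
chr2	387323	387573	148	31
chr2	389719	390031	185	33
chr2	391474	391769	177	28
chr2	394094	394387	153	33
chr2	395632	396085	271	46
chr2	401276	401693	251	47
chr2	402634	402941	203	31
chr2	407559	407905	186	38
chr2	412195	412669	271	40
chr2	418640	419096	289	38
chr2	420989	421471	294	59
chr2	429562	429840	168	35
chr2	432029	432415	672	47
chr2	435428	435811	699	38
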