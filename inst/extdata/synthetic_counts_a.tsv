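chrom	start	end	read_count	background_count
chr1	11278	11720	793	42
chr1	16731	17075	198	39
chr1	24126	24419	162	41
chr1	27242	27457	119	16
chr1	34650	34868	139	21
chr1	39483	39794	181	25
chr1	41132	41451	185	35
chr1	44130	44511	694	40
chr1	53996	54236	146	21
chr1	58510	58817	586	45
chr1	65382	65839	273	51
chr1	70524	70898	205	26
chr1	72253	72745	266	47
chr1	76445	76651	378	21
chr1	81562	82029	297	49
chr1	84076	84557	319	37
chr1	87596	88061	276	47
chr1	91030	91294	176	31
chr1	92901	93335	292	39
chr1	95081	95302	145	21
chr1	104493	104726	178	28
chr1	109685	109936	409	23
chr1	111234	111707	315	48
chr1	114115	114572	296	38
chr1	116799	117041	134	25
chr1	118628	118940	205	22
chr1	123597	123908	199	25
chr1	128608	128909	219	34
chr1	131918	132350	266	43
chr1	139014	139393	723	38
chr1	142023	142516	283	38
chr1	144471	144871	259	33
chr1	147820	148309	289	51
chr1	152998	153231	135	23
chr1	164825	165182	206	32
chr1	166774	167182	738	39
chr1	168905	169233	586	29
chr1	181114	181387	153	25
chr1	183260	183720	268	58
chr1	185177	185560	654	33
chr1	190512	190938	268	36
chr1	193208	193642	797	38
chr1	206031	206317	177	34
chr1	211049	211264	377	19
chr1	218134	218409	159	23
chr1	219647	219893	142	20
chr1	224996	225261	175	24
chr1	226809	227186	242	23
chr1	231959	232206	149	33
chr1	236376	236654	502	37
chr1	243408	243744	200	29
chr1	255081	255525	260	52
chr1	257588	258087	895	45
chr1	260280	260743	838	40
chr1	265245	265657	238	39
chr1	268949	269308	624	32
chr1	272957	273414	294	38
chr1	276842	277067	141	18
chr1	278277	278545	170	37
chr1	290340	290824	313	54
chr1	299275	299764	267	42
chr1	313429	313668	137	24
chr1	315342	315814	279	55
chr1	318638	318934	170	38
chr1	324189	324513	200	33
chr1	326017	326398	243	42
chr1	333065	333394	621	41
chr1	337310	337521	109	31
chr1	340185	340434	132	23
chr1	341889	342120	139	24
chr1	350669	350878	395	9
chr1	356024	356354	218	23
chr1	358938	359209	167	31
chr1	361033	361367	615	44
chr1	372369	372663	168	34
chr1	376686	376998	189	35
chr1	380829	381127	517	35
chr1	383715	383920	121	26
chr1	385496	385702	120	16
chr1	390955	391356	262	31
chr1	395218	395660	281	43
chr1	396976	397343	190	33
chr1	399888	400094	359	26
chr1	404703	405195	836	53
chr1	407304	407530	428	26
chr1	419128	419481	214	23
chr1	421680	422103	739	55
chr1	432737	432948	129	29
chr1	441761	442050	504	35
chr1	446644	446951	169	35
chr1	452013	452332	169	38
chr1	459046	459324	492	24
chr1	460745	460947	372	12
chr1	465878	466222	220	35
chr1	468297	468786	324	54
chr1	472204	472587	248	39
chr1	477645	478118	859	45
chr1	486804	487259	265	43
chr1	489823	490075	160	29
chr1	492635	492855	144	22
chr2	1099	1309	128	17
chr2	13235	13456	126	21
chr2	21416	21620	120	21
chr2	28577	28958	258	42
chr2	31020	31281	144	29
chr2	35125	35537	743	30
chr2	37237	37714	288	56
chr2	40361	40845	888	60
chr2	44999	45223	109	26
chr2	48073	48411	200	25
chr2	51893	52239	211	40
chr2	57377	57716	193	36
chr2	61019	61356	203	41
chr2	62752	63043	173	28
chr2	65037	65505	817	39
chr2	67230	67484	146	24
chr2	70583	70856	477	22
chr2	74388	74625	127	21
chr2	75824	76072	150	28
chr2	77630	77874	154	12
chr2	85439	85869	771	45
chr2	90652	90873	124	22
chr2	92842	93234	704	32
chr2	103892	104272	215	29
chr2	109476	109915	289	39
chr2	116343	116723	269	36
chr2	118767	119015	156	24
chr2	127261	127739	326	56
chr2	133263	133566	189	35
chr2	136755	137159	268	51
chr2	142623	142889	154	19
chr2	160208	160523	161	37
chr2	165214	165523	166	27
chr2	171406	171772	688	36
chr2	177455	177778	536	29
chr2	184925	185367	842	42
chr2	190212	190591	210	42
chr2	202765	203249	314	50
chr2	206059	206511	269	52
chr2	208091	208389	201	33
chr2	209674	210001	225	40
chr2	214271	214506	143	23
chr2	215711	216094	189	36
chr2	222484	222751	462	29
chr2	226715	226941	127	23
chr2	229469	229773	170	29
chr2	231235	231726	289	42
chr2	233671	233884	107	19
chr2	241851	242232	230	28
chr2	246323	246756	273	43
chr2	249264	249480	123	27
chr2	252822	253199	679	36
chr2	254432	254768	618	30
chr2	256738	257053	199	25
chr2	258767	259155	682	35
chr2	262440	262840	230	30
chr2	264511	264720	145	13
chr2	275880	276245	222	41
chr2	277922	278408	293	50
chr2	280862	281101	143	40
chr2	283063	283327	144	30
chr2	284525	284828	167	26
chr2	287121	287465	213	40
chr2	290121	290472	228	38
chr2	302989	303414	243	40
chr2	304803	305040	167	26
chr2	306344	306566	385	17
chr2	310206	310474	170	26
chr2	311776	312014	142	22
chr2	313789	314060	165	31
chr2	317592	317907	539	33
chr2	319970	320178	132	16
chr2	322024	322249	145	28
chr2	326640	326846	116	21
chr2	328187	328416	155	18
chr2	330647	331055	680	46
chr2	332415	332820	259	50
chr2	334503	334937	806	43
chr2	337113	337558	234	51
chr2	341372	341588	113	27
chr2	343743	344081	205	37
chr2	345439	345901	277	31
chr2	347688	348075	234	33
chr2	353445	353940	926	49
chr2	362664	363053	217	37
chr2	365048	365378	228	36
chr2	366980	367345	217	29
chr2	374248	374690	267	50
chr2	376817	377253	269	51
chr2	382064	382361	539	24
chr2	384223	384550	204	27
chr2	395765	396214	252	39
chr2	401285	401504	396	23
chr2	402658	403112	299	51
chr2	407581	408048	284	39
chr2	412372	412860	903	49
chr2	414516	414869	196	45
chr2	429510	429816	525	26
chr2	431947	432410	266	54
chr2	435318	435726	212	47
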