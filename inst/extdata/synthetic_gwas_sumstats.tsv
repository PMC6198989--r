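variant_id	effect_allele	other_allele	beta	p
rs1839190	G	C	-0.0223755661839651	8.21992418692096e-06
rs1319002	T	C	-0.0689299956603486	3.928241338144e-07
rs5069745	A	C	0.0260250736338632	2.35568981139893e-05
rs5595452	T	G	0.0896947436515066	8.24059892087124e-07
rs4670933	G	A	0.0738297850133395	2.91165807376998e-09
rs6116153	G	C	0.0360508269882456	3.56837443936336e-09
rs7432320	T	C	-0.239241618378061	1.76560117724344e-07
rs1573970	G	A	-0.051670295258813	2.77807313633676e-05
rs4993756	G	A	-0.176452288972416	1.91987216394854e-07
rs0330293	C	T	0.0943414026852583	2.4579374276404e-06
rs7715439	G	C	0.0391802499281756	3.28504070829496e-06
rs4729023	G	A	0.0637152671030164	5.57437968909723e-06
rs3898628	A	G	-0.0513910644667753	3.57988193414023e-08
rs0664071	G	C	0.101515041744313	2.53217973701313e-09
rs5185266	T	C	-0.0787976067964678	1.97012941970511e-06
rs2721071	T	G	-0.146969752782385	1.95395251635134e-09
rs8604288	C	G	0.0215419717236767	1.74075604302061e-07
rs4601528	T	G	0.196632084356423	2.472510676267e-09
rs3812949	A	T	-0.059145284206634	8.64586465849405e-06
rs6436376	G	A	0.0869996815232775	1.78732357844882e-05
rs2848960	A	C	0.134746759441	4.33762514260686e-06
rs8573951	C	A	0.172782686196672	3.83215955612782e-06
rs8633510	G	T	0.0520589205065	1.78696173209561e-07
rs7392570	T	A	-0.106432921818359	5.90235973478248e-06
rs7805817	A	T	0.144179810559627	5.85129201000316e-06
rs5818169	C	A	-0.0563675503329857	7.35411995792028e-08
rs9413944	T	G	-0.0829037703794451	2.04948759181498e-05
rs6445653	A	T	-0.100914578914867	1.2348327751381e-06
rs2499107	A	G	0.147413884860411	4.22201947788644e-05
rs6650641	A	T	-0.0533620805861686	2.89676030224348e-07
rs2887236	G	C	0.0598480779848986	3.15701605735818e-07
rs3516501	T	A	0.0320287197281781	2.93142349471784e-09
rs8341348	A	T	0.0309377018579502	1.25765591044213e-07
rs7918755	C	A	-0.16779809343088	4.36489137672094e-09
rs1368332	C	G	0.0296889620211557	2.45936935179002e-05
rs8758026	A	G	-0.0669158047597975	1.29376359840697e-09
rs5762725	A	T	0.1613779763594	1.11337973119984e-09
rs2245053	T	A	-0.00488381635198781	4.19736458764045e-07
rs5753524	C	T	0.0860689995330427	6.37342378624366e-09
rs0376032	A	G	-0.0273296622469851	3.5188865313186e-07
rs5801008	C	T	0.0488976683924042	4.38226764326523e-08
rs9146506	A	T	0.0356962174221589	1.58967547772831e-05
rs4677991	G	C	0.023098291100423	5.07995539989572e-07
rs1124075	C	G	0.0628961374539724	6.73005093344294e-05
rs2564951	A	G	0.0782333531552984	4.16724056572015e-08
rs6084333	C	A	0.086834404775139	7.01549678144341e-05
rs4070463	C	A	-0.0203812816827358	8.37437988475819e-09
rs7089440	C	G	-0.117094379629888	2.05468687593395e-05
rs0395610	C	A	0.0537565295901779	2.81618231706509e-08
rs6481652	A	C	-0.0531548374267915	5.46099000913878e-06
rs5758698	G	T	-0.04267085437758	6.69132940375212e-06
rs9982922	C	A	-0.143246179186531	1.9278952415263e-05
rs2165567	A	T	-0.0306390686489092	1.10407114935289e-08
rs4255591	G	T	-0.0309462195774639	7.85938360236659e-09
rs5175741	A	G	0.127753844352603	1.74634087091006e-08
rs4435422	T	A	0.000363459830048921	1.8292012093526e-07
rs8607142	A	C	-0.0536490797868964	1.52658290065166e-07
rs5331566	G	A	0.119103170442445	1.13394502142394e-08
rs2432282	G	C	0.133742758978454	5.64574463857862e-08
rs6038841	A	G	-0.0330345024968578	4.15079985770667e-07
rx6274188	T	C	-0.0926680503134173	0.00348964931653875
rx7072681	T	C	0.0807587454401214	0.0040156920679774
rx5775681	A	C	-0.110524007225088	0.0043035995256651
rx7886065	A	G	-0.123819634401415	0.0616355443327594
rx8422996	G	C	-0.0546087449474524	0.0260028176276344
rx9967713	A	C	-0.134951210582562	0.00713282351030243
rx0842763	C	G	0.0871536964756637	0.221198851992965
rx4727358	A	T	-0.0967374703401068	0.000518866883709683
rx8939622	T	A	0.097947775806471	0.366557676548298
rx0570019	G	T	0.0160279585542415	0.00339867067565861
rx5586107	T	A	0.0929301771957152	0.494222619686968
rx2897733	C	A	0.0599852895766984	0.110192913133359
rx1143615	A	T	-0.0978581862643065	0.00233487662351995
rx7601080	T	C	-0.009388162050337	0.534133314929217
rx1397351	G	A	0.270252808747549	0.0189119730785824
rx1871495	T	C	-0.0975575895734021	0.0530955457142489
rx9319252	T	G	-0.125978814507177	0.000357314960560685
rx9903395	T	A	-0.0633016666162345	0.0156735093728185
rx4199652	C	G	-0.0967392752352866	0.0692557272788295
rx9440275	A	T	-0.0339749810175956	0.0697265467918624
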