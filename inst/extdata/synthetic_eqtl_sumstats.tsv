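variant_id	effect_allele	other_allele	beta	p
rs1839190	G	C	-0.185682467880561	0.0113158655539164
rs1319002	T	C	-0.227565120755351	0.00126392332715541
rs5069745	A	C	-0.0557455590310253	0.0101801250452199
rs5595452	G	T	-0.168299728570961	8.09743125487585e-05
rs4670933	A	G	0.155946182523357	0.00247435258203116
rs6116153	C	G	-0.0825629461180363	0.0420669973459283
rs7432320	T	C	-0.511443656125741	0.0248930470862552
rs1573970	G	A	-0.296344236975019	0.0410624138413991
rs4993756	G	A	-0.347958238372748	0.0458589253170262
rs0330293	C	T	0.198308513595614	0.0025498745114971
rs7715439	C	G	0.00851720314883561	0.00545948806637572
rs4729023	A	G	-0.22450184595907	0.010645688065296
rs3898628	G	A	0.203373214125233	0.0483173779483601
rs0664071	G	C	0.193762782165367	0.005243594398482
rs5185266	C	T	0.0780810577611972	0.0349122491069813
rs2721071	G	T	0.306638247129689	0.0158940214141025
rs8604288	G	C	0.188836012047967	0.013265123237021
rs4601528	T	G	0.383592939429999	0.00362615701326192
rs3812949	T	A	0.127361306432858	0.003493870194213
rs6436376	A	G	-0.188358372039628	0.0281093617383908
rs2848960	A	C	0.392142320360687	0.0261921092707245
rs8573951	A	C	-0.217181949922853	0.0275776566150598
rs8633510	G	T	0.0186889260567516	0.000592947747698054
rs7392570	A	T	0.307812920070517	0.0255406536382695
rs7805817	T	A	-0.244632664470683	0.0334930249441471
rs5818169	C	A	-0.0866489567428397	0.015780973460204
rs9413944	G	T	0.328394683519292	0.0431936539755005
rs6445653	A	T	-0.334422148691139	0.00866958691701177
rs2499107	A	G	0.305867952763084	0.0330359659905902
rs6650641	T	A	0.307522408065416	0.00522585033935262
rs2887236	C	G	-0.225743993303191	0.0445867604571173
rs3516501	A	T	-0.217127654850435	0.00529321232734947
rs8341348	T	A	-0.0352882630583312	0.0149481537842071
rs7918755	A	C	0.199414103169274	0.0364907057396984
rs1368332	G	C	-0.268581577942297	0.0365418080928803
rs8758026	G	A	0.273474586977168	0.0158024989019206
rs5762725	T	A	-0.507917158556649	0.0115393449408237
rs2245053	T	A	0.127831676137191	0.0405230116980339
rs5753524	C	T	0.0153805876490449	0.0300034802843372
rs0376032	G	A	0.240504572145324	0.01445306731275
rs5801008	C	T	0.0594442790010494	0.0247334041396682
rs9146506	A	T	0.198189762762616	0.0465460949554204
rs4677991	C	G	-0.0221149347446543	0.0422975155298593
rs1124075	G	C	-0.0283015189111944	0.0151624640707287
rs2564951	A	G	0.0821897335139934	0.0450067527368257
rs6084333	C	A	0.0962367425742497	0.046489692581339
rs4070463	C	A	0.177811978675126	0.0216274981834632
rs7089440	C	G	-0.292942503050381	0.0230290302185176
rs0395610	C	A	0.216305605180891	0.00765612081297161
rs6481652	C	A	0.0124441082108677	0.007874356513998
rs5758698	G	T	-0.156911345892761	0.0356740524685101
rs9982922	C	A	-0.349070456014299	0.0239891298560845
rs2165567	T	A	-0.0774603715627168	0.0300340921949006
rs4255591	G	T	0.102743879923006	0.0310262694460482
rs5175741	A	G	0.376225885250861	0.0140548628010878
rs4435422	T	A	-0.137235161684982	0.0442005207823655
rs8607142	C	A	0.0243807340939389	0.00778100868104817
rs5331566	G	A	-0.101909788014739	0.0355897958845554
rs2432282	C	G	-0.199497013384328	0.0297122235270874
rs6038841	G	A	-0.132707491160488	0.0293442374136774
rx8132268	A	T	0.105734451474291	0.882295735870022
rx5056094	G	T	-0.31846972684879	0.240987168485997
rx0309052	C	T	0.281704771840928	0.0897426917012781
rx4697406	C	G	-0.448319036152133	0.973565667316318
rx1766439	T	A	0.267751122979806	0.97969717030297
rx5133035	C	A	-0.00881516392890301	0.768301524788141
rx2183710	T	A	0.298530765641717	0.399469782158965
rx0611424	C	A	-0.129230191352113	0.201283547641477
rx9529927	A	T	0.25320949896118	0.315959841040196
rx3816228	A	G	0.306505948914451	0.610162934078602
rx1665617	G	A	-0.90774991047061	0.718009884013794
rx2605042	C	T	-0.201901351021233	0.0562778406052385
rx6000804	T	G	-0.312175075823356	0.376024936030153
rx7404887	A	C	0.286417080644501	0.342084923313232
rx6173260	G	C	-0.307994620477317	0.604882713995175
rx2577074	A	G	0.195958595239491	0.959580570513848
rx9499214	A	C	-0.0631392728056992	0.274959845169913
rx1686851	C	T	0.517456108113754	0.334112676416524
rx2901847	A	T	0.0421611452486289	0.565880675743101
rx4061795	C	G	0.215066991938113	0.959561160388403
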