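variant_id	effect_allele	other_allele	effect_allele_frequency	beta	standard_error	p_value	n	n_cases
rs000001	G	A	0.80324828643351787	0.054564682469258857	0.00790475811621188	5.100019688451106e-12	420531	58874
rs000002	C	T	0.33878077936824408	0.038440711551065113	0.0066395804069285863	7.0541791289930087e-09	420531	58874
rs000003	C	A	0.66232699537649753	0.022549817410343974	0.0066448984975295868	0.0006899212400386319	420531	58874
rs000004	T	G	0.67835581169929349	0.0054927847469615374	0.0067275374090476087	0.4142354304571329	420531	58874
rs000005	A	G	0.46130829341709606	0.044253794602245551	0.0063038660283122735	2.2170328950553832e-12	420531	58874
rs000006	A	G	0.68127827560529108	-0.00047150415199546502	0.0067437994610066851	0.94425996709046001	420531	58874
rs000007	T	G	0.42413989421911535	-0.062600212437957756	0.0063585734531215682	7.2032829182485257e-23	420531	58874
rs000008	T	G	0.32288821507245297	0.030690595063431435	0.0067207302942510734	4.9580128724489528e-06	420531	58874
rs000009	C	A	0.83892926326952866	0.010071094047486252	0.008548733064769767	0.23876459334748687	420531	58874
rs000010	A	G	0.15714340899139642	-0.065176125188853448	0.0086347113076327055	4.4147289556051766e-14	420531	58874
rs000011	A	G	0.86169456571806213	0.040462803297983879	0.0091028304031299297	8.785943954836019e-06	420531	58874
rs000012	G	A	0.90779713953379537	-0.024049851463386947	0.010861908711369274	0.026818738801892058	420531	58874
rs000013	T	G	0.6831977569963783	0.004089458195619405	0.0067546898233532019	0.54489663332522431	420531	58874
rs000014	G	A	0.51420693171676246	-0.00018416823374429016	0.006287501917870527	0.97663237602679931	420531	58874
rs000015	T	C	0.45451081050559872	0.0026978030717878078	0.0063111364217566177	0.6690391562548581	420531	58874
rs000016	T	G	0.80800854756962504	-0.017964997853744731	0.0079785473394383306	0.0243435922593923	420531	58874
rs000017	T	C	0.14927997242193669	0.052396242479822962	0.0088181736970656035	2.8182771323679325e-09	420531	58874
rs000018	G	A	0.82689368557184928	0.019265669453628554	0.008305991034393655	0.020368441585619838	420531	58874
rs000019	C	A	0.1679622643860057	-0.032452001787957444	0.0084061159966712321	0.00011314471935549936	420531	58874
rs000020	C	T	0.3158841130090877	-0.0012119201301615838	0.0067599583581594508	0.85771845458918761	420531	58874
rs000021	T	C	0.092542603937909002	-0.03700665486504591	0.010843981568585711	0.00064335791103811984	420531	58874
rs000022	C	A	0.15079325756523759	0.038310199652445899	0.0087816287345027447	1.285615375019028e-05	420531	58874
rs000023	A	G	0.66239225938916202	0.029037511904119875	0.0066452133464703746	1.2442393347368803e-05	420531	58874
rs000024	C	T	0.81499863509088755	-0.045512409535820954	0.0080929497489737531	1.8689836010250586e-08	420531	58874
rs000025	A	G	0.76761421074625102	-0.0057512911618371526	0.0074404030872382374	0.43953355025437507	420531	58874
rs000026	T	C	0.31307645163033154	0.046934662571434617	0.0067763112677530664	4.3203589696654878e-12	420531	58874
rs000027	C	T	0.60372245758771892	-0.014551937142410314	0.0064247222115279591	0.0235132398763849	420531	58874
rs000028	C	A	0.78402493067551404	-0.011262665856722781	0.0076367048044249921	0.14026443331451161	420531	58874
rs000029	T	G	0.050476683862507345	-0.026610031575359596	0.014354052362592762	0.063762899961265732	420531	58874
rs000030	A	C	0.069014230207540092	0.029470431346269046	0.012397436864362591	0.017447509375668951	420531	58874
rs000031	T	G	0.44701491619925943	-0.031452868834463313	0.0063205523800282113	6.4816256410697786e-07	420531	58874
rs000032	A	C	0.31126075370702888	-0.0141187526615624	0.0067870828846152793	0.037503641729290105	420531	58874
rs000033	T	G	0.20858126177918163	-0.016858359053110242	0.007734494611448226	0.029284682754530028	420531	58874
rs000034	T	C	0.92604150304105126	0.017886098473058484	0.012007801137601096	0.1363452641363504	420531	58874
rs000035	A	G	0.65764644781593229	0.026957008964247728	0.0066227611460234559	4.69409419081087e-05	420531	58874
rs000036	A	C	0.66285927577409887	-0.077874255333337167	0.0066474713471767043	1.0695656152530197e-31	420531	58874
rs000037	A	G	0.098712655296549198	-0.040083655431554503	0.010535488978507966	0.00014201533191121962	420531	58874
rs000038	C	T	0.91950789773836727	-0.03532845239223216	0.011550968079959568	0.0022245987246373618	420531	58874
rs000039	G	A	0.069924064003862446	0.0075159524850736004	0.012322539414427382	0.54190462939120965	420531	58874
rs000040	C	A	0.63263073994312435	0.026250117469872925	0.0065184779175702645	5.6485410014658034e-05	420531	58874
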