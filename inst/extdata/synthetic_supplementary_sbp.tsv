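variant_id	effect_allele	other_allele	effect_allele_frequency	beta	standard_error	p_value	n	n_cases
rs000001	G	A	0.80324828643351787	0.068967745968190663	0.0020435278788352401	1.0926532035868239e-249	757601	
rs000002	C	T	0.33878077936824408	0.034494421670088204	0.0017164557682669403	7.9494058025306947e-90	757601	
rs000003	C	A	0.66232699537649753	0.021559860816852537	0.0017178305941940013	3.9434646483807777e-36	757601	
rs000004	T	G	0.67835581169929349	0.010495369882106326	0.0017391942990766761	1.5934105727466131e-09	757601	
rs000005	A	G	0.46130829341709606	0.071503444255623161	0.0016296673198486033	0	757601	
rs000006	A	G	0.68127827560529108	-0.0042142856897563787	0.0017433983437870747	0.015636891175393897	757601	
rs000007	T	G	0.42413989421911535	-0.082132018296048548	0.0016438102127915	0	757601	
rs000008	T	G	0.32288821507245297	0.030675404616065251	0.0017374345325339626	9.219101687791482e-70	757601	
rs000009	C	A	0.83892926326952866	0.022867700423040697	0.0022100074524417476	4.3027040556456776e-25	757601	
rs000010	A	G	0.15714340899139642	-0.087891354977452651	0.0022322344369592544	0	757601	
rs000011	A	G	0.86169456571806213	0.045503785323738957	0.0023532519821137096	2.6457279696130172e-83	757601	
rs000012	G	A	0.90779713953379537	-0.051577928308526935	0.002808006638877843	2.3626712581004806e-75	757601	
rs000013	T	G	0.6831977569963783	0.016779920230702468	0.0017462137062230335	7.3032137762090442e-22	757601	
rs000014	G	A	0.51420693171676246	0.0052282935482761165	0.0016254368911108202	0.0012974344925558799	757601	
rs000015	T	C	0.45451081050559872	0.0071023069214712561	0.0016315468525901742	1.342182587601098e-05	757601	
rs000016	T	G	0.80800854756962504	-0.019407546918032422	0.0020626037737081766	4.9970722371477955e-21	757601	
rs000017	T	C	0.14927997242193669	0.061280302032742685	0.0022796628973893022	3.6338259455304222e-159	757601	
rs000018	G	A	0.82689368557184928	0.028451020380158825	0.0021472540956475267	4.514732236516424e-40	757601	
rs000019	C	A	0.1679622643860057	-0.045791132468220606	0.0021731382718327445	1.4546922286400324e-98	757601	
rs000020	C	T	0.3158841130090877	0.0011786178054705334	0.0017475757210499137	0.50003786174650899	757601	
rs000021	T	C	0.092542603937909002	-0.048070774544664831	0.0028033721370338285	6.5634972866490293e-66	757601	
rs000022	C	A	0.15079325756523759	0.042235342976912067	0.0022702153407746315	2.9757532990832946e-77	757601	
rs000023	A	G	0.66239225938916202	0.036786782555637602	0.0017179119885363287	9.9670156432234209e-102	757601	
rs000024	C	T	0.81499863509088755	-0.071475418560906293	0.0020921789371546192	8.5305269997516136e-256	757601	
rs000025	A	G	0.76761421074625102	0.0056055310665522025	0.0019234834153065157	0.003565326604642584	757601	
rs000026	T	C	0.31307645163033154	0.046167041287688441	0.0017518032541588764	4.6169717511261905e-153	757601	
rs000027	C	T	0.60372245758771892	-0.0075554843350880592	0.0016609109045478438	5.3901345891160082e-06	757601	
rs000028	C	A	0.78402493067551404	-0.014274075121375795	0.0019742310821973786	4.8230204451365527e-13	757601	
rs000029	T	G	0.050476683862507345	-0.0061489158796640886	0.0037107911141594902	0.097512119878050821	757601	
rs000030	A	C	0.069014230207540092	0.041816404265361796	0.003204969397667731	6.5783844207117276e-39	757601	
rs000031	T	G	0.44701491619925943	-0.052875188836600279	0.0016339810539852161	1.0122778767145789e-229	757601	
rs000032	A	C	0.31126075370702888	-0.020573498695634081	0.0017545879186652979	9.4292779005637696e-32	757601	
rs000033	T	G	0.20858126177918163	-0.03099093233862716	0.001999511577056298	3.5095814975021772e-54	757601	
rs000034	T	C	0.92604150304105126	0.029920803569976454	0.0031042412718324378	5.4886591141793525e-22	757601	
rs000035	A	G	0.65764644781593229	0.024002463360629007	0.0017121076746180596	1.1886627491777752e-44	757601	
rs000036	A	C	0.66285927577409887	-0.085993665312366907	0.0017184957239683276	0	757601	
rs000037	A	G	0.098712655296549198	-0.046266665360689477	0.0027236210302991328	1.0216951831611533e-64	757601	
rs000038	C	T	0.91950789773836727	-0.049726360433224572	0.0029861413786365426	2.908042596695383e-62	757601	
rs000039	G	A	0.069924064003862446	0.0010110141685501157	0.0031856070054545695	0.75096332689310086	757601	
rs000040	C	A	0.63263073994312435	0.04840321526188783	0.0016851485088211985	1.946406563325003e-181	757601	
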