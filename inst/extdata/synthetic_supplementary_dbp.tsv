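variant_id	effect_allele	other_allele	effect_allele_frequency	beta	standard_error	p_value	n	n_cases
rs000001	G	A	0.80324828643351787	0.11492173062389995	0.0020435278788352401	0	757601	
rs000002	C	T	0.33878077936824408	0.037343349731456761	0.0017164557682669403	6.0504391563421984e-105	757601	
rs000003	C	A	0.66232699537649753	0.047020793111622682	0.0017178305941940013	5.8789351164758304e-165	757601	
rs000004	T	G	0.67835581169929349	0.010179745695095825	0.0017391942990766761	4.8238111193243553e-09	757601	
rs000005	A	G	0.46130829341709606	0.010971787462839134	0.0016296673198486033	1.6673564296407146e-11	757601	
rs000006	A	G	0.68127827560529108	0.0092704521948249203	0.0017433983437870747	1.052253966125906e-07	757601	
rs000007	T	G	0.42413989421911535	-0.061521596445144711	0.0016438102127915	1.4642348705838727e-306	757601	
rs000008	T	G	0.32288821507245297	0.055377363541979314	0.0017374345325339626	6.3079417013410948e-223	757601	
rs000009	C	A	0.83892926326952866	-0.0021346301350173729	0.0022100074524417476	0.33409785976827133	757601	
rs000010	A	G	0.15714340899139642	-0.094058755644063324	0.0022322344369592544	0	757601	
rs000011	A	G	0.86169456571806213	-0.0083839448281149056	0.0023532519821137096	0.00036705175134646158	757601	
rs000012	G	A	0.90779713953379537	-0.0039934969078297645	0.002808006638877843	0.15497338041576816	757601	
rs000013	T	G	0.6831977569963783	-0.0087454169072206257	0.0017462137062230335	5.493661959957126e-07	757601	
rs000014	G	A	0.51420693171676246	0.0039965219917983815	0.0016254368911108202	0.013942667577395918	757601	
rs000015	T	C	0.45451081050559872	-0.012325576484803662	0.0016315468525901742	4.2036152644416177e-14	757601	
rs000016	T	G	0.80800854756962504	-0.067444966486131838	0.0020626037737081766	1.6166501720224862e-234	757601	
rs000017	T	C	0.14927997242193669	0.10155337657660113	0.0022796628973893022	0	757601	
rs000018	G	A	0.82689368557184928	0.036305904165664406	0.0021472540956475267	3.9240546649498742e-64	757601	
rs000019	C	A	0.1679622643860057	-0.035952793761793278	0.0021731382718327445	1.7634553518671353e-61	757601	
rs000020	C	T	0.3158841130090877	0.025737723969609883	0.0017475757210499137	4.281972857409926e-49	757601	
rs000021	T	C	0.092542603937909002	-0.041152801529417304	0.0028033721370338285	8.69105639359876e-49	757601	
rs000022	C	A	0.15079325756523759	0.020088808207199188	0.0022702153407746315	8.8421124999649016e-19	757601	
rs000023	A	G	0.66239225938916202	-0.014678601162535375	0.0017179119885363287	1.2915762866338203e-17	757601	
rs000024	C	T	0.81499863509088755	-0.054967938995512923	0.0020921789371546192	3.89760204306241e-152	757601	
rs000025	A	G	0.76761421074625102	-0.016050729806033694	0.0019234834153065157	7.1445861070932224e-17	757601	
rs000026	T	C	0.31307645163033154	0.031466125178725983	0.0017518032541588764	3.8568885847696795e-72	757601	
rs000027	C	T	0.60372245758771892	-0.038330173279471351	0.0016609109045478438	7.7371467099758948e-118	757601	
rs000028	C	A	0.78402493067551404	-0.042406687673993214	0.0019742310821973786	2.3897421150274069e-102	757601	
rs000029	T	G	0.050476683862507345	-0.018955874925863238	0.0037107911141594902	3.2505138550434635e-07	757601	
rs000030	A	C	0.069014230207540092	0.045461874674006378	0.003204969397667731	1.1377715079495972e-45	757601	
rs000031	T	G	0.44701491619925943	-0.066438750036446184	0.0016339810539852161	0	757601	
rs000032	A	C	0.31126075370702888	-0.0094916705016295493	0.0017545879186652979	6.3155281608982688e-08	757601	
rs000033	T	G	0.20858126177918163	-0.041710144608532417	0.001999511577056298	1.2324153048154019e-96	757601	
rs000034	T	C	0.92604150304105126	0.015602017341280246	0.0031042412718324378	5.0073121541542421e-07	757601	
rs000035	A	G	0.65764644781593229	0.068101226025110359	0.0017121076746180596	0	757601	
rs000036	A	C	0.66285927577409887	-0.084180926738516931	0.0017184957239683276	0	757601	
rs000037	A	G	0.098712655296549198	-0.066601526445375051	0.0027236210302991328	4.6414702360727269e-132	757601	
rs000038	C	T	0.91950789773836727	-0.017365679783723827	0.0029861413786365426	6.0480200450845896e-09	757601	
rs000039	G	A	0.069924064003862446	0.0091069098624936163	0.0031856070054545695	0.0042529032937627335	757601	
rs000040	C	A	0.63263073994312435	0.02574399061772327	0.0016851485088211985	1.0885990034186194e-52	757601	
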