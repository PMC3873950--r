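# ROOT-MTG 1
# UNIT: mm
# PLANT_ID: example_seedling
# SLOPE_DEG: 45
# FLEXED: no
# BLOCK: b1
# CONTAINER:           300           300           110
# SHOOT_DW_G: 5.456221
# ROOT_DW_G: 1.145081
# COLLAR: 0 0 0
# FEATURES: XX YY ZZ Diameter FineRootCount FineRootMeanLength
ENTITY	TOPO	PARENT	XX	YY	ZZ	Diameter	FineRootCount	FineRootMeanLength
S0001	/	-	-1.76303426583	-1.04066235843	-7.64047328595	9.51120676547	0	0
S0002	<	S0001	-2.67464111125	-1.57875452606	-11.5911099155	9.07034919039	0	0
S0003	<	S0002	-3.6533368712	-2.15644711972	-15.8324902187	7.13547844564	0	0
S0004	<	S0003	-5.34928222249	-3.15750905212	-23.1822198309	6.94994193477	0	0
S0005	<	S0004	-8.02392333374	-4.73626357818	-34.7733297464	5.35316431486	1	           20
S0006	<	S0005	-9.63294284891	-5.68601598848	-41.7463482864	4.98128478533	0	0
S0007	<	S0006	-10.698564445	-6.31501810424	-46.3644396619	 4.7701313766	0	0
S0008	<	S0007	-12.3303184096	-7.27818992801	-53.4359826361	3.73704947162	0	0
S0009	<	S0008	-12.651275343	-7.46764047114	-54.826915826	3.57644892856	0	0
S0010	<	S0009	-13.3732055562	-7.8937726303	-57.9555495773	2.59517313791	0	0
S0011	<	S0010	-14.0360707783	-8.28504062701	-60.8282129847	 1.8629142817	0	0
S0012	<	S0011	-16.0478466675	-9.47252715636	-69.5466594928	1.82996726674	0	0
S0013	<	S0012	-18.7224877787	-11.0512816824	-81.1377694083	1.26879156661	0	0
S0014	<	S0013	 -21.39712889	-12.6300362085	-92.7288793238	1.18064975307	0	0
S0015	<	S0014	-24.0717700012	-14.2087907345	-104.319989239	1.09863107237	0	0
S0016	<	S0015	-25.3824288082	-14.9824304258	         -110	1.02231015594	0	0
S0017	<	S0016	-30.6524517454	-18.093155274	         -110	0.986869611708	0	0
S0018	<	S0017	-40.9864714471	-24.1929943543	         -110	 0.9512911852	0	0
S0019	<	S0018	-51.3204911487	-30.2928334347	         -110	0.885205838741	0	0
S0020	<	S0019	-60.6792715569	-35.8170201623	         -110	0.823711382101	0	0
S0064	+	S0011	-20.622009283	-18.0028452353	-63.3161212645	          0.8	0	0
S0065	<	S0064	-28.1437078831	-27.2245525229	-64.8601953788	          0.8	0	0
S0066	<	S0065	-35.7850789055	-36.3498148333	-66.3895863243	          0.8	0	0
S0067	<	S0066	-42.9710519515	-45.7261101069	-68.4983485975	          0.8	0	0
S0068	<	S0067	-50.5132423205	-54.7390340376	-70.923748906	          0.8	0	0
S0069	<	S0068	-58.2557596488	-63.3785988292	-73.9915405601	          0.8	0	0
S0070	<	S0069	-65.8480608229	-72.2448733567	-76.7747291785	          0.8	0	0
S0071	<	S0070	-73.3388796295	-81.315670442	-79.1429086148	          0.8	0	0
S0072	<	S0071	-80.8841177941	-90.4597223291	 -81.00185889	          0.8	0	0
S0073	<	S0072	-88.8034687592	-99.1915172429	-83.2467726692	          0.8	0	0
S0074	<	S0073	-94.0509304367	-104.857450257	-84.5947159256	          0.8	0	0
S0075	+	S0009	-1.7649206521	-12.2775075435	-56.3606890462	1.09666080963	0	0
S0076	<	S0075	8.94796569283	-17.5189829625	-57.6877163982	          0.8	0	0
S0077	<	S0076	19.7541846488	-22.4535281883	 -59.38356288	          0.8	0	0
S0078	<	S0077	30.6693839073	-26.9956549265	-61.4396537927	          0.8	0	0
S0079	<	S0078	 41.706401961	-31.3955419586	-63.1204948282	          0.8	0	0
S0080	<	S0079	52.9258521446	-35.2129114169	-65.0050711725	          0.8	0	0
S0081	<	S0080	64.0470327215	-39.642379627	-65.8412254354	          0.8	0	0
S0082	<	S0081	75.0511860312	-44.4284468092	-65.8878179635	          0.8	0	0
S0083	<	S0082	86.0179469074	-49.2870810895	-65.5359247765	          0.8	0	0
S0084	<	S0083	97.1759281367	-53.693299432	-65.244901057	          0.8	0	0
S0085	<	S0084	 99.629273877	-54.6621724686	-65.1876019881	          0.8	0	0
S0031	+	S0008	-15.8931740095	-18.6415275375	-54.9126743257	 1.5113255144	0	0
S0032	<	S0031	-19.603841128	-29.8622232065	-56.9928037065	          0.8	0	0
S0033	<	S0032	-22.914999325	-41.2285920937	-58.9528776119	          0.8	0	0
S0034	<	S0033	-25.8917094259	-52.6349270407	-61.1966957981	          0.8	0	0
S0035	<	S0034	-28.8210051131	-64.024834314	-63.5819083841	          0.8	0	0
S0036	<	S0035	-31.7548021162	-75.4384939659	-65.8449171108	          0.8	0	0
S0037	<	S0036	-34.9714738866	-86.7715754593	-68.1283983533	          0.8	0	0
S0038	<	S0037	-38.4214725074	-98.1377928149	-69.8332773931	          0.8	0	0
S0039	<	S0038	-40.3601887557	-105.585858055	-71.4450095724	          0.8	0	0
S0055	+	S0006	-6.8521848603	5.95783846369	-42.5758291514	2.04244823211	0	0
S0056	<	S0055	-4.16327639489	17.6332681561	-43.2497080446	          0.8	0	0
S0057	<	S0056	-1.0946647346	29.2246983143	-43.7212686074	          0.8	0	0
S0058	<	S0057	1.62612239493	40.9087484551	-44.0046229868	          0.8	0	0
S0059	<	S0058	4.57696935388	52.5325129258	-44.429595638	          0.8	0	0
S0060	<	S0059	 7.4864371388	64.1330333865	-45.4108816568	          0.8	0	0
S0061	<	S0060	10.1120489382	75.7679261945	-46.7282396278	          0.8	0	0
S0062	<	S0061	13.0120177622	87.4061960365	-47.103547375	          0.8	0	0
S0063	<	S0062	13.9265213873	90.5150621538	-47.0418675507	          0.8	0	0
S0040	+	S0003	7.86619570534	-5.36469224299	-16.8362493766	2.97578735201	0	0
S0041	<	S0040	19.3490527223	-8.64368147507	-18.0161749433	          0.8	0	0
S0042	<	S0041	30.8217548744	-11.930022073	-19.2719897407	          0.8	0	0
S0043	<	S0042	42.4555462879	-14.8131281595	-19.8573072963	          0.8	0	0
S0044	<	S0043	54.1101051495	-17.5835668285	-20.5615283716	          0.8	0	0
S0045	<	S0044	 65.749644324	-20.3028518319	-21.6229504722	          0.8	0	0
S0046	<	S0045	77.5126015095	-22.5085666656	-22.4991127428	          0.8	0	0
S0047	<	S0046	89.2610572518	-24.6618709047	-23.6554295352	          0.8	0	0
S0048	<	S0047	101.132708006	-26.2227564814	-24.4476066478	          0.8	0	0
S0049	<	S0048	112.912356988	-27.7474706472	-26.1549779003	          0.8	0	0
S0050	<	S0049	124.718035575	-28.5817647881	-28.1373770475	          0.8	0	0
S0051	<	S0050	136.610236366	-29.4899035351	-29.4605718007	          0.8	0	0
S0052	<	S0051	 148.45114769	-30.6835743688	-30.999392442	          0.8	0	0
S0053	<	S0052	          150	-30.8777975709	-31.1513975972	          0.8	0	0
S0054	<	S0053	          150	-36.1359100442	-35.2665609431	          0.8	0	0
S0021	+	S0001	9.66998133494	1.41287169461	-10.336085447	3.88369149734	0	0
S0022	<	S0021	21.0013835478	4.34552126594	-12.9816270516	          0.8	0	0
S0023	<	S0022	32.4943964848	7.05396775195	-15.1205452976	          0.8	0	0
S0024	<	S0023	  44.00380764	9.82147977075	-17.0888776085	          0.8	0	0
S0025	<	S0024	55.5480656134	12.5394325065	-18.9172213318	          0.8	0	0
S0026	<	S0025	66.9010016408	16.1192332965	-20.4324341419	          0.8	0	0
S0027	<	S0026	 78.087342945	20.3727840025	-21.311680762	          0.8	0	0
S0028	<	S0027	 89.376389428	24.2721625377	-22.4745550218	          0.8	0	0
S0029	<	S0028	100.696810028	28.2445639123	-22.735523886	          0.8	0	0
S0030	<	S0029	107.895702168	30.5781605326	-23.4159254188	          0.8	0	0
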