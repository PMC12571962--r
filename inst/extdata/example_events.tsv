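onset	duration	trial_type	trial_id	arousal_class	valence_rating	arousal_rating	rating_onset	rating_duration	button_press_times
10	6	NEG	1	HIGH	4	7	16	5.32696663076058	16.7379235367552,18.3575257712982
22.16722641605884	6	NEG	2	HIGH	2	6	28.16722641605884	7.926709619350731	28.7086748176833,31.9052391354787
32.986076809465885	6	NEU	3	HIGH	5	6	38.986076809465885	2.1891798856668174	40.0153621285391,40.7001714880246
46.586032764054835	6	NEU	4	HIGH	5	4	52.586032764054835	2.280445400159806	53.8546199625819,54.7900284315227
57.0803700806573	6	POS	5	HIGH	7	6	63.0803700806573	5.812595351599157	65.1940004599603,67.0527838196756
70.88655786588788	6	POS	6	LOW	8	2	76.88655786588788	7.381603870540857	78.7400575762285,79.1550746406686
84.01341836992651	6	NEU	7	HIGH	4	5	90.01341836992651	7.6004249094985425	92.3434658326562,93.6132730996216
97.86196222901344	6	NEG	8	HIGH	3	6	103.86196222901344	2.287989451084286	104.938783043464,106.052223718006
108.31896993983537	6	NEG	9	LOW	2	3	114.31896993983537	4.967116716783494	114.864872765456,115.514030951840
122.22917849663645	6	NEG	10	HIGH	5	5	128.22917849663645	6.488309565465897	131.16573508715,133.37153807246
134.71105650346726	6	POS	11	HIGH	8	8	140.71105650346726	3.314584366977215	141.823933206106,141.895868753567
148.42076556570828	6	NEG	12	HIGH	2	6	154.42076556570828	3.5832674871198833	155.911846028613,155.940861733429
159.22971241734922	6	POS	13	LOW	8	2	165.22971241734922	7.430586987640709	168.105379435630,171.060610665412
170.0918291443959	6	POS	14	LOW	6	3	176.0918291443959	2.980375414248556	177.343918021582,178.489435633916
183.77953003533185	6	NEU	15	LOW	6	2	189.77953003533185	5.616622471250594	191.813723398827,193.953372469510
196.66799223888665	6	POS	16	HIGH	6	4	202.66799223888665	3.335372714791447	204.362355077325,205.575609292933
209.7147977920249	6	NEU	17	LOW	3	3	215.7147977920249	7.068276088219136	218.648515273806,221.813099879582
220.8559075947851	6	NEU	18	LOW	5	3	226.8559075947851	7.586335903964937	229.077842860896,234.330597029621
232.23054311797023	6	NEU	19	HIGH	6	6	238.23054311797023	5.512087772600353	240.062356628735,241.282967608935
243.5961167840287	6	NEU	20	HIGH	5	6	249.5961167840287	7.464338813442737	249.936371440269,251.364649800659
256.74795597139746	6	NEU	21	LOW	4	2	262.74795597139746	6.381173529196531	264.836664122114,266.919993989452
268.2059559356421	6	POS	22	HIGH	8	6	274.2059559356421	5.305434602778405	275.601607198674,277.294257135796
280.86644615605474	6	NEG	23	LOW	5	1	286.86644615605474	7.555458707734942	287.326626423116,289.949872776356
292.35769319627434	6	NEG	24	HIGH	1	6	298.35769319627434	4.972694199997932	301.109393942985,302.747284551292
302.84177667368203	6	POS	25	HIGH	9	4	308.84177667368203	6.468551213853061	310.898062641248,313.523622581764
316.1651627542451	6	NEG	26	HIGH	2	6	322.1651627542451	2.79128699330613	322.988788989743,323.616095239615
327.83843188360333	6	NEG	27	LOW	4	3	333.83843188360333	5.87754179071635	337.980522704705,338.122187989411
338.1665572253987	6	NEG	28	LOW	1	3	344.1665572253987	2.5029068742878735	346.136962190512,346.296765568396
348.8706676084548	6	NEU	29	HIGH	5	4	354.8706676084548	3.499621505383402	356.463168054078,357.900634336583
359.59451215714216	6	NEG	30	LOW	2	2	365.59451215714216	3.175749596208334	365.979278180749,367.792525923386
372.2882223678753	6	NEU	31	LOW	4	3	378.2882223678753	6.315228248015046	381.206538093739,382.743639697615
384.7162042874843	6	NEG	32	LOW	2	3	390.7162042874843	7.402176532428712	392.326071515169,395.586055367067
395.7543095126748	6	POS	33	HIGH	7	6	401.7543095126748	4.0361185017973185	403.115869450550,404.014510164212
408.11576132662594	6	POS	34	HIGH	8	6	414.11576132662594	5.174382016994059	416.308925335214,418.168990573861
419.74973418936133	6	POS	35	LOW	7	3	425.74973418936133	7.912339624483138	426.138461541366,428.705661819727
433.2154497904703	6	NEU	36	HIGH	5	5	439.2154497904703	6.140063900500536	443.781066885364,444.694916597476
443.6480934107676	6	POS	37	LOW	6	2	449.6480934107676	5.804883316159248	450.141134839242,453.563479094144
454.9356531566009	6	POS	38	LOW	8	2	460.9356531566009	3.358582451939583	463.66757397163,464.23274193348
465.6088024666533	6	NEU	39	LOW	5	3	471.6088024666533	3.2745685284025967	473.445132772267,473.704903815706
475.8151221321896	6	NEG	40	LOW	1	4	481.8151221321896	5.099196458701044	484.213104766303,484.725704191380
488.0282478639856	6	NEU	41	LOW	6	1	494.0282478639856	7.697630282025784	500.774322692609,500.868534138294
498.595932492055	6	POS	42	LOW	6	1	504.595932492055	6.637855623383075	508.551577644741,509.765403077103
509.2314707906917	6	POS	43	LOW	6	3	515.2314707906917	3.9365376755595207	517.343194230775,518.169194605474
522.3467068448663	6	POS	44	LOW	6	2	528.3467068448663	2.1577347037382424	529.559851953167,529.766112013216
534.1217030771077	6	NEG	45	HIGH	1	5	540.1217030771077	2.337897508405149	541.552895241033,541.903779542936
544.6477930760011	6	NEG	46	LOW	2	3	550.6477930760011	6.031735211610794	551.763310418144,552.866592479759
556.9135721093044	6	POS	47	HIGH	8	5	562.9135721093044	2.8881858200766146	565.521670281601,565.532239234240
570.00909665972	6	NEU	48	LOW	4	2	576.00909665972	6.767380210570991	578.214800780117,582.231215313426
581.6939528826624	6	POS	49	HIGH	7	5	587.6939528826624	5.099675650708377	589.834761137727,591.338783596305
591.9372752122581	6	NEU	50	LOW	5	2	597.9372752122581	2.1349715893156826	598.558628081984,599.621472265174
603.4790609441698	6	NEU	51	HIGH	6	5	609.4790609441698	3.997166738845408	610.017013237172,611.054376117022
615.3286814047024	6	NEG	52	LOW	5	3	621.3286814047024	4.446895583998412	623.531231833502,624.372704996341
625.4943767301738	6	NEG	53	HIGH	2	5	631.4943767301738	6.060416627209634	635.197729558497,637.191506611870
637.13727934286	6	NEU	54	HIGH	7	5	643.13727934286	2.8991617071442306	644.120424218585,644.776507370288
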