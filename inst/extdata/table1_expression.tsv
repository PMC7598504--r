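pathway	gene	fpkm_10mM	fpkm_0.8mM	printed_log2fc	q
Arginine biosynthesis	argA	1422	256	-2.48	<0.001
Arginine biosynthesis	argB	2500	739	-1.76	<0.001
Arginine biosynthesis	argC	2154	446	-2.27	<0.001
Arginine biosynthesis	argD_2	1990	521	-1.93	<0.001
Arginine biosynthesis	argE	789	355	-1.15	<0.001
Arginine biosynthesis	argI	5296	454	-3.54	<0.001
Arginine biosynthesis	argG	3559	1825	-0.96	<0.001
Arginine biosynthesis	argH	2533	894	-1.50	<0.001
Putrescine biosynthesis	speA	533	850	0.67	0.003
Putrescine biosynthesis	adi	13	11	-0.27	0.35
Putrescine biosynthesis	speB	246	487	0.99	<0.001
Putrescine biosynthesis	speC	42	77	0.89	<0.001
Putrescine biosynthesis	speF	10	8	-0.22	0.59
Putrescine import	potF	498	548	0.13	0.73
Putrescine import	potG	224	311	0.47	0.053
Putrescine import	potH	83	118	0.51	0.17
Putrescine import	potI	114	154	0.42	0.25
Putrescine import	yeeF	450	1210	1.42	<0.001
Putrescine export	sapB	60	70	0.22	0.85
Putrescine export	sapC	69	78	0.17	0.90
Putrescine export	sapD	101	126	0.31	0.64
Putrescine export	sapF	73	92	0.33	0.21
Putrescine export	potE	7	6	-0.16	0.85
Putrescine degradation	speE	238	662	1.47	<0.001
Putrescine degradation	oat	225	84	-1.42	<0.001
Putrescine degradation	ydcW	71	61	-0.21	0.51
DNA topoisomerases	topA	289	298	0.04	0.94
DNA topoisomerases	gyrA	377	674	0.84	<0.001
DNA topoisomerases	gyrB	364	499	0.45	0.081
DNA topoisomerases	topB	122	160	0.39	0.13
DNA topoisomerases	parC	126	186	0.56	0.012
DNA topoisomerases	parE	295	383	0.38	0.15
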