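peptide	preceding	following	abundance_active	abundance_control
SPLGSDLGPQMLRELQETNAALQDVRELLR	Q	Q	1000000	0
GSDLGPQMLRELQETNAALQDVRELLR	L	Q	1000000	0
LGPQMLRELQETNAALQDVRELLR	D	Q	1000000	0
LRELQETNAALQDVRELLR	M	Q	1000000	0
NTVMECDACGMQQ	K	S	1000000	0
QQVREITFLKNTVMECDACGMQQ	R	S	1000000	0
VRTGLPSVRPLLHCAPGFCFPGVACIQTESGAR	S	C	230350000	1000000
EITFLKNTVMECDACGMQQS	R	V	102010000	1000000
QQVREITFLKNTVMECDACGMQQS	R	V	1000000	0
LPSVRPLLHCAPGFCFPGVACIQTESGAR	G	C	1000000	0
TGLPSVRPLLHCAPGFCFPGVACIQT	R	E	1000000	0
INECETGQHNCVPNSVCINTR	D	G	1000000	0
ANKQVCTDINECETGQHNCV	K	P	1000000	0
FCPDGSPSECHEHADCVLERD	R	G	1000000	0
QDDFDADKVVDKIDVCPENAEVTLTDFR	C	A	1000000	0
FRAFQTVVLDPEGDAQIDPNWVVLNQGR	D	E	1000000	0
AFQTVVLDPEGDAQIDPNWVVLNQGREIVQTMNSDPGLAVGYTA	R	F	1000000	0
QMEQTYWQANPFRA	K	V	1000000	0
QMEQTYWQANPFRAVAEPGIQLKA	K	V	1000000	0
LRQAFEGKPIPNPLLGLDSTR	Q	T	1000000	0
EITFLKNTVMECDACGMQQSVR	R	T	0	1000000
QQVREITFLKNTVMECDACGMQQSVR	R	T	0	1000000
FCPDGSPSECHEHADCVLERDGSR	R	S	0	1000000
DGSRSCVCAVGWAGNGILCGR	R	D	0	1000000
AVKSSTGPGEQLRNALWHTGDTESQVR	K	L	1000000	150820000
MEAASR	-	T	14460.0544849	1000000
TSNLADGK	R	E	24735.5501621	1000000
EVNVVEQAQSPLGSDLGPQMLR	K	E	32629.1758022	1000000
ELQETNAALQDVR	R	E	39638.9288669	1000000
EITFLK	R	N	46182.2049908	1000000
NTVMECDACGMQQSVR	K	T	52445.9467523	1000000
CESAQLR	R	S	58533.0067384	1000000
SGTDLLQR	R	T	64507.2930589	1000000
TELVQDQK	R	S	70411.9305112	1000000
SNTTGAEK	K	E	76277.8451379	1000000
ETNSLGEK	K	L	82128.2957452	1000000
LNLTQSTK	K	A	87981.4679413	1000000
ALSEALNR	K	S	93852.054699	1000000
SVLVEEK	R	A	99752.2685333	1000000
QVCTDINECETGQHNCVPNSVCINTR	K	G	105692.516681	1000000
GQDVQGR	R	S	111681.867174	1000000
SVQQALQR	R	V	117728.380149	1000000
VNTEVTLR	R	A	123839.349489	1000000
FCPDGSPSECHEHADCVLER	R	D	130021.483136	1000000
SCVCAVGWAGNGILCGR	R	D	136281.040466	1000000
DTLANGGR	R	G	142623.938989	1000000
GTDALTEK	R	Q	149055.838734	1000000
DGIGDACDPDADGDGVPNEK	R	D	155582.210165	1000000
DNCPLVR	K	N	162208.389783	1000000
NTAELVR	R	E	168939.626418	1000000
EGTTDVVR	R	G	175781.120432	1000000
GVSQDEER	R	D	182738.057479	1000000
DLQVTLEK	R	T	189815.638091	1000000
TSQLGESK	K	L	197019.104049	1000000
LVTGETNR	K	N	204353.762293	1000000
NGDQTLDR	R	E	211825.006984	1000000
ELNTTSLK	R	E	219438.340171	1000000
EQLQDNGR	K	S	227199.391495	1000000
DETDNGK	R	T	235113.937223	1000000
TTGEGQDR	K	N	243187.918907	1000000
NLQGGVTR	R	A	251427.461916	1000000
ASNAAGSK	R	G	259838.894025	1000000
GQTDQDDQR	K	L	268428.764289	1000000
LVPNPGQEDADR	R	D	277203.862351	1000000
DGVGDVCQDDFDADK	R	V	286171.238369	1000000
IDVCPENAEVTLTDFR	K	A	295338.223713	1000000
AFQTVVLDPEGDAQIDPNWVVLNQGR	R	E	304712.452605	1000000
EIVQTMNSDPGLAVGYTAFNGVDFVQSEVK	R	V	314301.884859	1000000
VADDQETK	K	L	324114.829883	1000000
LDEVAEAK	K	Q	334159.972126	1000000
QQSNTAGAAQK	K	Q	344446.398147	1000000
QMEQTYWQANPFR	K	A	354983.625499	1000000
AVAEPGIQLK	R	A	365781.633651	1000000
SSTGPGEQLR	K	N	376850.897157	1000000
NALWHTGDTESQVR	R	L	388202.42134	1000000
LLEGEGR	R	L	399847.780748	1000000
LDGALESR	R	D	411799.160693	1000000
DTSLVNTR	R	Q	424069.402207	1000000
QSNNTSQR	R	V	436672.050777	1000000
FYEGPELVADSNVVLDTTMR	R	G	449621.409286	1000000
LGVFCFSQDNGDTR	R	L	462932.595603	1000000
LGDTNSVR	R	V	476621.605362	1000000
VNQESQQSVQLR	R	Q	490705.380494	1000000
QAFEGKPIPNPLLGLDSTR	R	T	505201.884183	1000000
TGDESA	R	-	520130.182971	1000000
MEAASRTSNLADGK	-	E	535510.536867	1000000
TSNLADGKEVNVVEQAQSPLGSDLGPQMLR	R	E	551364.498408	1000000
ELQETNAALQDVRELLR	R	Q	567715.021749	1000000
ELLRQQVR	R	E	584586.583032	1000000
QQVREITFLK	R	N	602005.313433	1000000
CESAQLRSGTDLLQR	R	T	619999.146527	1000000
SGTDLLQRTELVQDQK	R	S	638597.981817	1000000
TELVQDQKSNTTGAEK	R	E	657833.866589	1000000
SNTTGAEKETNSLGEK	K	L	677741.198568	1000000
ETNSLGEKLNLTQSTK	K	A	698356.952257	1000000
LNLTQSTKALSEALNR	K	S	719720.932308	1000000
ALSEALNRSVLVEEK	K	A	741876.057826	1000000
SVLVEEKANK	R	Q	764868.68217	1000000
GQDVQGRSVQQALQR	R	V	788748.953624	1000000
SVQQALQRVNTEVTLR	R	A	813571.223247	1000000
VNTEVTLRAQR	R	F	839394.507382	1000000
AQRFCPDGSPSECHEHADCVLER	R	D	866283.013685	1000000
SCVCAVGWAGNGILCGRDTLANGGR	R	G	894306.741261	1000000
DTLANGGRGTDALTEK	R	Q	923542.167552	1000000
GTDALTEKQVVR	R	K	954073.037199	1000000
KDNCVTVPNSGQEDVDR	R	D	985991.271262	1000000
DNCPLVRNPDQR	K	N	1019398.0191	1000000
NPDQRNTAELVR	R	E	1054404.88017	1000000
NTAELVREGTTDVVR	R	G	1091135.32907	1000000
EGTTDVVRGVSQDEER	R	D	1129726.38515	1000000
GVSQDEERDLQVTLEK	R	T	1170330.57775	1000000
DLQVTLEKTSQLGESK	R	L	1213118.27109	1000000
TSQLGESKLVTGETNR	K	N	1258280.42921	1000000
LVTGETNRNGDQTLDR	K	E	1306031.92286	1000000
NGDQTLDRELNTTSLK	R	E	1356615.50869	1000000
ELNTTSLKEQLQDNGR	R	S	1410306.64838	1000000
DETDNGKTTGEGQDR	R	N	1467419.38561	1000000
TTGEGQDRNLQGGVTR	K	A	1528313.56711	1000000
NLQGGVTRASNAAGSK	R	G	1593403.7866	1000000
ASNAAGSKGQTDQDDQR	R	L	1663170.56017	1000000
GQTDQDDQRLVPNPGQEDADR	K	D	1738174.42262	1000000
LVPNPGQEDADRDGVGDVCQDDFDADK	R	V	1819073.89287	1000000
VVDKIDVCPENAEVTLTDFR	K	A	1906648.63087	1000000
VADDQETKLDEVAEAK	K	Q	2001829.65937	1000000
LDEVAEAKQQSNTAGAAQK	K	Q	2105739.35096	1000000
QQSNTAGAAQKQMEQTYWQANPFR	K	A	2219745.14823	1000000
QMEQTYWQANPFRAVAEPGIQLK	K	A	2345532.97233	1000000
AVAEPGIQLKAVK	R	S	2485209.47392	1000000
AVKSSTGPGEQLR	K	N	2641447.58045	1000000
SSTGPGEQLRNALWHTGDTESQVR	K	L	2817698.87006	1000000
NALWHTGDTESQVRLLEGEGR	R	L	3018512.44513	1000000
LLEGEGRLDGALESR	R	D	3250029.97078	1000000
LDGALESRDTSLVNTR	R	Q	3520785.19939	1000000
DTSLVNTRQSNNTSQR	R	V	3843058.21945	1000000
QSNNTSQRVR	R	F	4235307.50628	1000000
VRFYEGPELVADSNVVLDTTMR	R	G	4726872.10654	1000000
FYEGPELVADSNVVLDTTMRGGR	R	L	5367982.8162	1000000
GGRLGVFCFSQDNGDTR	R	L	6254086.32098	1000000
LGVFCFSQDNGDTRLGDTNSVR	R	V	7597656.90398	1000000
LGDTNSVRVNQESQQSVQLR	R	Q	10022226.3576	1000000
QAFEGKPIPNPLLGLDSTRTGDESA	R	-	17144145.8304	1000000
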