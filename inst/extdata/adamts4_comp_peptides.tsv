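peptide	preceding	following	abundance_active	abundance_control
SVRTGLPSVRPLLHCAPGFCFPGVACIQTESGAR	Q	C	1000000	0
VRTGLPSVRPLLHCAPGFCFPGVACIQTESGAR	S	C	142610000	1000000
NTVMECDACGMQQS	K	V	1000000	0
EITFLKNTVMECDACGMQQS	R	V	1000000	0
VRPLLHCAPGFCFPGVACIQTESGAR	S	C	1000000	0
CIQTESGAR	A	C	1000000	0
TGLPSVRPLLHCAPGFCFPGVACIQTE	R	S	1000000	0
QVCTDINECETGQHNCVPN	K	S	1000000	0
PDGSPSECHEHADCVLER	C	D	1000000	0
SCVCAVGWAGNGILCGRD	R	T	1000000	0
NCVTVPNSGQEDVDRDGIGDACDPDADGDGVPNEKDNCPLVR	D	N	1000000	0
VTVPNSGQEDVDRDGIGDACDPDADGDGVPNEKDNCPLVR	C	N	1000000	0
VDRDGIGDACDPDADGDGVPNEKDNCPLVR	D	N	1000000	0
KDNCVTVPNSGQEDVDRDGIGD	R	A	1000000	0
CDPDADGDGVPNEKDNCPLVR	A	N	1000000	0
DADGDGVPNEKDNCPLVR	P	N	1000000	0
DGDGVPNEKDNCPLVR	A	N	1000000	0
VPNEKDNCPLVR	G	N	1000000	0
DNCVTVPNSGQEDVDRDGIGDACDPDADGDGVPN	K	E	1000000	0
PDQADVDHDFVGDACDSDQDQDGDGHQDSR	N	D	1000000	0
GVGDVCQDDFDADKVVDKIDVCPENAEVTLTDFR	D	A	1000000	0
LVPNPGQEDADRDGVGD	R	V	1000000	0
IDVCPENAEVTLT	K	D	1000000	0
RAFQTVVLDPEGDAQIDPNWVVLNQGR	F	E	1000000	0
TVVLDPEGDAQIDPNWVVLNQGR	Q	E	1000000	0
VVLDPEGDAQIDPNWVVLNQGR	T	E	1000000	0
WVVLNQGR	N	E	1000000	0
AFQTVVLDPEGDAQIDPNWVVLNQ	R	G	1000000	0
EIVQTMNSDPGLAVGYTAF	R	N	1000000	0
GPELVADSNVVLDTTMRGGR	E	L	1000000	0
FYEGPELVADSNVVLDTT	R	M	1000000	0
FYEGPELVADSNVVLDTTM	R	R	1000000	0
VRFYEGPELVADSNVVLDTTM	R	R	1000000	0
LGVFCFS	R	Q	1000000	0
LRQAFEGKPIPNPLLGLDSTR	Q	T	1000000	0
EITFLKNTVMECDACGMQQSVR	R	T	1000000	71300000
ANKQVCTDINECETGQHNCVPNSVCINTR	K	G	1000000	738000000
AQRFCPDGSPSECHEHADCVLERDGSR	R	S	0	1000000
DNCVTVPNSGQEDVDR	K	D	0	1000000
DGIGDACDPDADGDGVPNEKDNCPLVR	R	N	0	1000000
DGIGDACDPDADGDGVPNEKDNCPLVRNPDQR	R	N	0	1000000
DGVGDVCQDDFDADKVVDK	R	I	0	1000000
MEAASR	-	T	62013.0139443	1000000
TSNLADGK	R	E	95282.7933619	1000000
EVNVVEQAQSPLGSDLGPQMLR	K	E	118917.954758	1000000
ELQETNAALQDVR	R	E	138951.685553	1000000
EITFLK	R	N	157017.826468	1000000
NTVMECDACGMQQSVR	K	T	173836.600146	1000000
CESAQLR	R	S	189799.23371	1000000
SGTDLLQR	R	T	205145.838401	1000000
TELVQDQK	R	S	220036.304762	1000000
SNTTGAEK	K	E	234583.58178	1000000
ETNSLGEK	K	L	248871.147682	1000000
LNLTQSTK	K	A	262962.965655	1000000
ALSEALNR	K	S	276909.526101	1000000
SVLVEEK	R	A	290751.702105	1000000
QVCTDINECETGQHNCVPNSVCINTR	K	G	304523.31222	1000000
GQDVQGR	R	S	318252.883042	1000000
SVQQALQR	R	V	331964.897055	1000000
VNTEVTLR	R	A	345680.698367	1000000
FCPDGSPSECHEHADCVLER	R	D	359419.164683	1000000
SCVCAVGWAGNGILCGR	R	D	373197.215581	1000000
DTLANGGR	R	G	387030.203752	1000000
GTDALTEK	R	Q	400932.220961	1000000
DGIGDACDPDADGDGVPNEK	R	D	414916.340865	1000000
DNCPLVR	K	N	428994.814395	1000000
NTAELVR	R	E	443179.229023	1000000
EGTTDVVR	R	G	457480.640264	1000000
GVSQDEER	R	D	471909.681575	1000000
DLQVTLEK	R	T	486476.657354	1000000
TSQLGESK	K	L	501191.622584	1000000
LVTGETNR	K	N	516064.451909	1000000
NGDQTLDR	R	E	531104.900282	1000000
ELNTTSLK	R	E	546322.656908	1000000
EQLQDNGR	K	S	561727.393846	1000000
DETDNGK	R	T	577328.810374	1000000
TTGEGQDR	K	N	593136.674036	1000000
NLQGGVTR	R	A	609160.859106	1000000
ASNAAGSK	R	G	625411.383119	1000000
GQTDQDDQR	K	L	641898.442001	1000000
LVPNPGQEDADR	R	D	658632.444257	1000000
DGVGDVCQDDFDADK	R	V	675624.04465	1000000
IDVCPENAEVTLTDFR	K	A	692884.177717	1000000
AFQTVVLDPEGDAQIDPNWVVLNQGR	R	E	710424.091482	1000000
EIVQTMNSDPGLAVGYTAFNGVDFVQSEVK	R	V	728255.381659	1000000
VADDQETK	K	L	746390.026674	1000000
LDEVAEAK	K	Q	764840.423765	1000000
QQSNTAGAAQK	K	Q	783619.42648	1000000
QMEQTYWQANPFR	K	A	802740.383847	1000000
AVAEPGIQLK	R	A	822217.181517	1000000
SSTGPGEQLR	K	N	842064.285197	1000000
NALWHTGDTESQVR	R	L	862296.7867	1000000
LLEGEGR	R	L	882930.452953	1000000
LDGALESR	R	D	903981.778354	1000000
DTSLVNTR	R	Q	925468.040871	1000000
QSNNTSQR	R	V	947407.362339	1000000
FYEGPELVADSNVVLDTTMR	R	G	969818.773447	1000000
LGVFCFSQDNGDTR	R	L	992722.283942	1000000
LGDTNSVR	R	V	1016138.95867	1000000
VNQESQQSVQLR	R	Q	1040091.00014	1000000
QAFEGKPIPNPLLGLDSTR	R	T	1064601.83827	1000000
TGDESA	R	-	1089696.22832	1000000
MEAASRTSNLADGK	-	E	1115400.35781	1000000
TSNLADGKEVNVVEQAQSPLGSDLGPQMLR	R	E	1141741.96358	1000000
ELQETNAALQDVRELLR	R	Q	1168750.46018	1000000
ELLRQQVR	R	E	1196457.08097	1000000
QQVREITFLK	R	N	1224895.03354	1000000
CESAQLRSGTDLLQR	R	T	1254099.67117	1000000
SGTDLLQRTELVQDQK	R	S	1284108.68252	1000000
TELVQDQKSNTTGAEK	R	E	1314962.30179	1000000
SNTTGAEKETNSLGEK	K	L	1346703.54209	1000000
ETNSLGEKLNLTQSTK	K	A	1379378.45535	1000000
LNLTQSTKALSEALNR	K	S	1413036.42214	1000000
ALSEALNRSVLVEEK	K	A	1447730.47594	1000000
SVLVEEKANK	R	Q	1483517.66656	1000000
GQDVQGRSVQQALQR	R	V	1520459.46875	1000000
SVQQALQRVNTEVTLR	R	A	1558622.24267	1000000
VNTEVTLRAQR	R	F	1598077.7543	1000000
AQRFCPDGSPSECHEHADCVLER	R	D	1638903.76531	1000000
SCVCAVGWAGNGILCGRDTLANGGR	R	G	1681184.7038	1000000
DTLANGGRGTDALTEK	R	Q	1725012.42917	1000000
GTDALTEKQVVR	R	K	1770487.10753	1000000
KDNCVTVPNSGQEDVDR	R	D	1817718.21706	1000000
DNCPLVRNPDQR	K	N	1866825.70676	1000000
NPDQRNTAELVR	R	E	1917941.33744	1000000
NTAELVREGTTDVVR	R	G	1971210.23978	1000000
EGTTDVVRGVSQDEER	R	D	2026792.73267	1000000
GVSQDEERDLQVTLEK	R	T	2084866.45506	1000000
DLQVTLEKTSQLGESK	R	L	2145628.87759	1000000
TSQLGESKLVTGETNR	K	N	2209300.27722	1000000
LVTGETNRNGDQTLDR	K	E	2276127.27965	1000000
NGDQTLDRELNTTSLK	R	E	2346387.10318	1000000
ELNTTSLKEQLQDNGR	R	S	2420392.67514	1000000
DETDNGKTTGEGQDR	R	N	2498498.84245	1000000
TTGEGQDRNLQGGVTR	K	A	2581109.96581	1000000
NLQGGVTRASNAAGSK	R	G	2668689.2794	1000000
ASNAAGSKGQTDQDDQR	R	L	2761770.52585	1000000
GQTDQDDQRLVPNPGQEDADR	K	D	2860972.55454	1000000
LVPNPGQEDADRDGVGDVCQDDFDADK	R	V	2967017.82458	1000000
VVDKIDVCPENAEVTLTDFR	K	A	3080756.11853	1000000
VADDQETKLDEVAEAK	K	Q	3203195.30695	1000000
LDEVAEAKQQSNTAGAAQK	K	Q	3335541.80137	1000000
QQSNTAGAAQKQMEQTYWQANPFR	K	A	3479254.54792	1000000
QMEQTYWQANPFRAVAEPGIQLK	K	A	3636118.3078	1000000
AVAEPGIQLKAVK	R	S	3808344.99917	1000000
AVKSSTGPGEQLR	K	N	3998716.86	1000000
SSTGPGEQLRNALWHTGDTESQVR	K	L	4210793.66806	1000000
NALWHTGDTESQVRLLEGEGR	R	L	4449221.2176	1000000
LLEGEGRLDGALESR	R	D	4720205.83158	1000000
LDGALESRDTSLVNTR	R	Q	5032273.16016	1000000
DTSLVNTRQSNNTSQR	R	V	5397539.62033	1000000
QSNNTSQRVR	R	F	5833968.71035	1000000
VRFYEGPELVADSNVVLDTTMR	R	G	6369675.83228	1000000
FYEGPELVADSNVVLDTTMRGGR	R	L	7051955.91878	1000000
GGRLGVFCFSQDNGDTR	R	L	7968833.09698	1000000
LGVFCFSQDNGDTRLGDTNSVR	R	V	9311317.14273	1000000
LGDTNSVRVNQESQQSVQLR	R	Q	11621015.2079	1000000
QAFEGKPIPNPLLGLDSTRTGDESA	R	-	17855651.9073	1000000
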