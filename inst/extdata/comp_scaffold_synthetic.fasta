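>COMP_SCAFFOLD_SYNTHETIC synthetic COMP precursor scaffold; evidence-bearing residues fixed by published peptide data, gaps are deterministic filler
MEAASRTSNLADGKEVNVVEQAQSPLGSDLGPQMLRELQETNAALQDVRELLRQQVREIT
FLKNTVMECDACGMQQSVRTGLPSVRPLLHCAPGFCFPGVACIQTESGARCESAQLRSGT
DLLQRTELVQDQKSNTTGAEKETNSLGEKLNLTQSTKALSEALNRSVLVEEKANKQVCTD
INECETGQHNCVPNSVCINTRGQDVQGRSVQQALQRVNTEVTLRAQRFCPDGSPSECHEH
ADCVLERDGSRSCVCAVGWAGNGILCGRDTLANGGRGTDALTEKQVVRKDNCVTVPNSGQ
EDVDRDGIGDACDPDADGDGVPNEKDNCPLVRNPDQRNTAELVREGTTDVVRGVSQDEER
DLQVTLEKTSQLGESKLVTGETNRNGDQTLDRELNTTSLKEQLQDNGRSDETDVNPDQAD
VDHDFVGDACDSDQDQDGDGHQDSRDETDNGKTTGEGQDRNLQGGVTRASNAAGSKGQTD
QDDQRLVPNPGQEDADRDGVGDVCQDDFDADKVVDKIDVCPENAEVTLTDFRAFQTVVLD
PEGDAQIDPNWVVLNQGREIVQTMNSDPGLAVGYTAFNGVDFVQSEVKVADDQETKLDEV
AEAKQQSNTAGAAQKQMEQTYWQANPFRAVAEPGIQLKAVKSSTGPGEQLRNALWHTGDT
ESQVRLLEGEGRLDGALESRDTSLVNTRQSNNTSQRVRFYEGPELVADSNVVLDTTMRGG
RLGVFCFSQDNGDTRLGDTNSVRVNQESQQSVQLRQAFEGKPIPNPLLGLDSTRTGDESA
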