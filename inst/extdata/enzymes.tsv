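name	site	cut_offset
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
XbaI	TCTAGA	1
SalI	GTCGAC	1
PstI	CTGCAG	5
SmaI	CCCGGG	3
KpnI	GGTACC	5
SacI	GAGCTC	5
SphI	GCATGC	5
XhoI	CTCGAG	1
NcoI	CCATGG	1
NdeI	CATATG	2
NheI	GCTAGC	1
SpeI	ACTAGT	1
EcoRV	GATATC	3
ScaI	AGTACT	3
StuI	AGGCCT	3
PvuII	CAGCTG	3
HpaI	GTTAAC	3
DraI	TTTAAA	3
SspI	AATATT	3
ApoI	RAATTY	1
AflII	CTTAAG	1
AvrII	CCTAGG	1
BglII	AGATCT	1
ClaI	ATCGAT	2
MfeI	CAATTG	1
AluI	AGCT	2
HaeIII	GGCC	2
RsaI	GTAC	2
TaqI	TCGA	1
MseI	TTAA	1
DdeI	CTNAG	1
HinfI	GANTC	1
MboI	GATC	0
HhaI	GCGC	3
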