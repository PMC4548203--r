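drug_name	target	degree_immunome
Lapatinib	EGFR	137
Lidocaine	EGFR	137
Maraviroc	CCR5	46
Dasatinib	STAT5B	33
Chloroquine	TNF	22
Chloroquine	TLR9	22
Clenbuterol	TNF	22
Glucosamine	TNF	22
Infliximab	TNF	22
Alteplase	SERPINE1	18
Intravenous immunoglobulin	C3	30
Intravenous immunoglobulin	FCGR1A	13
Intravenous immunoglobulin	FCGR2A	11
Drotrecogin alfa	SERPINE1	18
Candesartan	AGTR1	16
Eprosartan	AGTR1	16
Irbesartan	AGTR1	16
Losartan	AGTR1	16
Olmesartan	AGTR1	16
Telmisartan	AGTR1	16
Valsartan	AGTR1	16
Adalimumab	FCGR1A	13
Adalimumab	FCGR2A	11
Adalimumab	TNF	22
Lenalidomide	TNFSF11	15
Thalidomide	PTGS2	7
Thalidomide	TNF	22
Etanercept	FCGR1A	13
Etanercept	FCGR2A	11
Etanercept	LTA	7
Etanercept	TNF	22
Abciximab	FCGR1A	13
Abciximab	FCGR2A	11
Alefacept	FCGR1A	13
Alefacept	FCGR2A	11
Alemtuzumab	FCGR1A	13
Alemtuzumab	FCGR2A	11
Daclizumab	FCGR1A	13
Daclizumab	FCGR2A	11
Efalizumab	FCGR1A	13
Efalizumab	FCGR2A	11
Rituximab	FCGR1A	13
Rituximab	FCGR2A	11
Canakinumab	IL1B	10
Gallium nitrate	IL1B	10
Minocycline	IL1B	10
Aminosalicylic acid	PTGS2	7
Balsalazide	PTGS2	7
Acetaminophen	PTGS2	7
Acetylsalicylic acid	PTGS2	7
Bromfenac	PTGS2	7
Etodolac	PTGS2	7
Etoricoxib	PTGS2	7
Gamma-homolinolenic acid	PTGS2	7
Carprofen	PTGS2	7
Celecoxib	PTGS2	7
Ibuprofen	PTGS2	7
Ketoprofen	PTGS2	7
Ketorolac	PTGS2	7
Lornoxicam	PTGS2	7
Mefenamic acid	PTGS2	7
Meloxicam	PTGS2	7
Mesalazine	PTGS2	7
Nabumetone	PTGS2	7
Naproxen	PTGS2	7
Nepafenac	PTGS2	7
Niflumic acid	PTGS2	7
Piroxicam	PTGS2	7
Salsalate	PTGS2	7
Sulindac	PTGS2	7
Tenoxicam	PTGS2	7
Indomethacin	PTGS2	7
Indomethacin	PLA2G2A	6
Suramin	PLA2G2A	6
Bosentan	EDNRA	4
Omalizumab	FCER1A	3
Enazepril	ACE	2
Captopril	ACE	2
Dinoprostone	PTGER3	2
Dipyridamole	PDE5A	2
Enalapril	ACE	2
Misoprostol	PTGER3	2
Pentoxifylline	PDE5A	2
Perindopril	ACE	2
Quinapril	ACE	2
Bildenafil	PDE5A	2
Tadalafil	PDE5A	2
Theophylline	PDE5A	2
Theophylline	ADORA2B	2
Vardenafil	PDE5A	2
Hydralazine	AOC3	1
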