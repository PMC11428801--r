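protein_name	pdb_id	res_id	logk
Alpha-1-antitrypsin	1QLP	232	6.86
Hydroperoxide reductase c	4MA9	46	5.94
Human DJ-1	1P5F	106	5.4
Creatine kinase	1I0E	283	5.6
O6-Alkylguanine-DNA alkyltransferase	1EH6	145	5.3
Tyrosine phosphatase 1b	2HNP	215	5.57
Papaya protease omega	1PPO	25	2.88
Yersinia protein tyrosine phosphatase	1YPT	403	4.67
Cathepsin B	1THE	29	3.6
DsbA protein	1DSB	30	3.5
Thioredoxin	2TRX	32	7.1
Thioredoxin	2TRX	35	9.9
Disulfide isomerase	1MEK	36	4.5
Ubiquitin conjugating enzyme	1JBB	87	11.1
Ubiquitin-conjugating enzyme 2B	1JAS	88	10.2
Human thioredoxin	1ERT	32	6.3
Glutaredoxin	1EGO	11	5.5
Glutaredoxin	1EGO	14	10.5
Acyl-coenzyme A binding protein	1NTI	86	9.9
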