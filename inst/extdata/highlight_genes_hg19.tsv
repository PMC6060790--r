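chrom	start	end	symbol
1	204485000	204542000	MDM4
2	15998000	16092000	MYCN
2	121554000	121750000	GLI2
3	41236000	41301000	CTNNB1
4	55095000	55164000	PDGFRA
5	1253000	1295000	TERT
6	135502000	135540000	MYB
7	55086000	55275000	EGFR
7	92234000	92465000	CDK6
7	116312000	116438000	MET
7	128828000	128853000	SMO
7	140419000	140624000	BRAF
8	38268000	38326000	FGFR1
8	67474000	67525000	MYBL1
8	128748000	128753000	MYC
9	21967000	22009000	CDKN2A/B
9	98205000	98279000	PTCH1
10	89623000	89728000	PTEN
10	104263000	104393000	SUFU
11	69455000	69469000	CCND1
12	4382000	4414000	CCND2
12	58142000	58146000	CDK4
12	69201000	69239000	MDM2
13	48877000	49056000	RB1
17	7571000	7590000	TP53
17	29421000	29709000	NF1
17	58677000	58744000	PPM1D
22	24129000	24176000	SMARCB1
22	29999000	30094000	NF2
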