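peptide	seq	amidated	length	mw_reported	net_charge_reported	gravy_reported	helicity_pct_reported	lcms_confirmed
phrynomantin-1Ba	GLVTNLLSSVR	FALSE	11	1158.4	1	0.84	72.7	FALSE
phrynomantin-1Bb	GLVPDLDLPVDL	FALSE	12	1265.5	-3	0.79	0	FALSE
phrynomantin-1Bc	GIVNNLLSTVL	FALSE	11	1142.4	0	1.40	81.8	FALSE
phrynomantin-1Bd	GPVFDYLSQVYPVR	FALSE	14	1639.9	0	0.05	50	FALSE
phrynomantin-1Be	GLVKDILSLDVL	FALSE	12	1284.5	-1	1.33	66.7	FALSE
phrynomantin-1Bf	GLVPDLDLPVDLPV	FALSE	14	1461.7	-3	0.86	0	FALSE
phrynomantin-1Ma	GLVKNQDLPVDLAAVF	FALSE	16	1699.0	-1	0.66	12.5	FALSE
phrynomantin-1Mb	GLVKNLNLPVDVPVDL	FALSE	16	1705.0	-1	0.66	0	TRUE
phrynomantin-1Mc	GLVKDLNLPVDVPVDLPV	FALSE	18	1902.2	-2	0.73	0	FALSE
phrynomantin-1Md	GLVKDLLSLDV	FALSE	11	1171.4	-1	1.05	63.6	TRUE
phrynomantin-2Ba	DYEAVSL	FALSE	7	795.8	-2	0.10	0	FALSE
phrynomantin-2Ma	DYEPASL	FALSE	7	793.8	-2	-0.73	0	FALSE
phrynomantin-3Ba	SEWPPVRGDNGEYDVEL	FALSE	17	1962.0	-4	-1.19	0	FALSE
phrynomantin-3Ma	SEWPPVRGDAGEYDVEL	FALSE	17	1919.0	-4	-0.88	0	FALSE
phrynomantin-3Mb	AEWRLL	FALSE	6	786.9	0	0.08	0	FALSE
phrynomantin-3Mc	AEWRLLKN	TRUE	8	1028.2	2	-0.86	0	FALSE
phrynomantin-4Ba	NAASRLYTPYSPTK	FALSE	14	1568.7	2	-0.95	0	FALSE
phrynomantin-4Bb	NARNFNSFDPFNTSD	FALSE	15	1745.8	-1	-1.28	0	FALSE
phrynomantin-4Ma	NTENFFNPFNPFV	FALSE	13	1586.7	-1	-0.46	0	TRUE
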