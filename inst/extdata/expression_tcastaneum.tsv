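sequence_name	type	rpkm	active
POP_Tc	POP	0	TRUE
DPP4.1_Tc	DPP4	1688	TRUE
DPP4.2_Tc	DPP4	533	TRUE
DPP8_Tc	DPP8	75	TRUE
DPP10.1_Tc	DPP10	8	FALSE
DPP10.2_Tc	DPP10	5	FALSE
PRCP.1_Tc	PRCP	27	TRUE
PRCP.2_Tc	PRCP	675	TRUE
APP1.1_Tc	APP1	2420	TRUE
APP1.2_Tc	APP1	8	TRUE
APP3_Tc	APP3	58	TRUE
XPD_Tc	XPD	1254	TRUE
LAP.1_Tc	LAP	86	FALSE
CND_Tc	CND	2462	FALSE
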