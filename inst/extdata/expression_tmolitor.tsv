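sequence_name	type	rpkm	active
POP_Tm	POP	25	TRUE
DPP4.1_Tm	DPP4	147	TRUE
DPP4.2_Tm	DPP4	102	TRUE
DPP8_Tm	DPP8	20	TRUE
DPP10.1_Tm	DPP10	370	FALSE
DPP10.2_Tm	DPP10	7	FALSE
PRCP_Tm	PRCP	53	TRUE
APP1_Tm	APP1	88	TRUE
APP2_Tm	APP2	3	TRUE
APP3_Tm	APP3	12	TRUE
XPD_Tm	XPD	148	TRUE
LAP_Tm	LAP	15	FALSE
CND_Tm	CND	625	FALSE
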