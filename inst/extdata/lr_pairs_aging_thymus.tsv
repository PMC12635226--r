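ligand	receptor	source
PLAU	PLAUR	aging_thymus
IL1B	IL1R1	aging_thymus
IL6	IL6ST	aging_thymus
PLA2G2A	ITGB1	aging_thymus
HAS2	CD44	aging_thymus
IGF2	INSR	aging_thymus
LPL	VLDLR	aging_thymus
APOE	LDLR	aging_thymus
COL1A1	ITGA5	aging_thymus
COL1A2	ITGA11	aging_thymus
FN1	ITGA5	aging_thymus
FBN1	ITGB1	aging_thymus
FBLN1	ITGB1	aging_thymus
COL1A1	ITGA11	aging_thymus
VCAN	ITGB1	aging_thymus
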