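protein1	protein2	combined_score
HSPA5	ERN1	0.950
HSPA5	ATF6	0.920
HSPA5	EIF2AK3	0.910
HSPA5	XBP1	0.780
ERN1	XBP1	0.880
ATF6	XBP1	0.640
EIF2AK3	ATF4	0.830
ATF4	DDIT3	0.760
DDIT3	BCL2	0.450
XBP1	DNAJB9	0.520
HSPA5	HSP90B1	0.700
HSP90B1	ERN1	0.410
ATF6	MBTPS1	0.620
MBTPS1	MBTPS2	0.580
HSPA5	CANX	0.390
CANX	CALR	0.350
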