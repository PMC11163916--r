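exposure	outcome	direction	method	scale	estimate	ci_low	ci_high
IL-18	MS	forward	ivw	or	0.706	0.538	0.925
ADA	MS	forward	ivw	or	0.808	0.673	0.970
SCF	MS	forward	ivw	or	0.898	0.816	0.987
IL-4	SLE	forward	ivw	or	1.384	1.081	1.771
IL-7	SLE	forward	weighted_median	or	1.401	1.010	1.943
IL-10RA	SLE	forward	ivw	or	1.266	1.004	1.596
CXCL5	SLE	forward	ivw	or	1.170	1.021	1.341
NTN	SLE	forward	ivw	or	1.225	1.004	1.496
FGF23	SLE	forward	ivw	or	0.644	0.460	0.902
MCP4	SLE	forward	ivw	or	0.665	0.476	0.929
CDCP1	HT	forward	ivw	or	1.127	1.008	1.261
IL-33	HT	forward	weighted_median	or	0.852	0.727	0.999
TRAIL	HT	forward	ivw	or	0.884	0.799	0.979
MS	CCL19	reverse	ivw	beta	0.035	0.012	0.058
MS	IL-13	reverse	ivw	beta	-0.019	-0.037	-0.001
MS	SLAM	reverse	weighted_median	beta	-0.028	-0.055	-0.001
SLE	ARTN	reverse	ivw	beta	0.021	0.006	0.036
SLE	Eotaxin	reverse	ivw	beta	-0.015	-0.029	-0.001
SLE	IL-22RA1	reverse	weighted_median	beta	-0.030	-0.053	-0.006
HT	ADA	reverse	weighted_median	beta	0.120	0.034	0.207
HT	MMP10	reverse	ivw	beta	-0.075	-0.143	-0.008
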