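gene	pred0	pred1	obs0	obs1
TUBB2A	0.55	0.45	0.55	0.45
CALU	0.9	0.1	0.9	0.1
USP2	0.2	0.8	0.2	0.8
UGT1A1	0.5498	0.4502	0.55	0.45
ASS1	0.9	0.1	0.9	0.1
UGT1A6	0.5999	0.4001	0.6	0.4
UGT1A10	0.5999	0.4001	0.6	0.4
UGT1A9	0.5998	0.4002	0.6	0.4
UGT1A7	0.3501	0.6499	0.35	0.65
TRIM29	0.45	0.55	0.45	0.55
PITX2	0.5	0.5	0.5	0.5
TSTA3	0.75	0.25	0.75	0.25
PCSK1	0.85	0.15	0.85	0.15
CXCL1	0.35	0.65	0.35	0.65
CCL13	0.25	0.75	0.25	0.75
TNIP3	0.7	0.3	0.7	0.3
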