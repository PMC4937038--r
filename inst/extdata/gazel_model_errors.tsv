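model	auc	ci_low	ci_high	false_positive	false_negative
RF	0.830	0.72	0.94	9	13
VarSelRF	0.845	0.76	0.94	14	11
Logistic regression	0.820	0.75	0.89	10	10
Univariate top-5	0.831	0.73	0.93	12	14
Univariate top-11	0.869	0.67	0.96	12	9
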