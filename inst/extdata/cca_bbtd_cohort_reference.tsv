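group	n	male	female	age_mean	age_sd	cea_median	cea_min	cea_max	ca19_9_median	ca19_9_min	ca19_9_max
BBTD	17	10	7	52.6	13	8.70	0.62	118.30	48.03	0.60	10000
CCA	19	10	9	60.9	13	9.87	1.47	410.40	4355.50	0.60	10000
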