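"statistic","value"
"n_with_onset",13
"median_days",18
"q1_days",13
"q3_days",35
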