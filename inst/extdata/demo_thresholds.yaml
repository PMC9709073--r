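min_a: 3
ror_lower_gt: 1
prr_ge: 2
chi2_ge: 4
ic025_gt: 0
ebgm05_gt: 2
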