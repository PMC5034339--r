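stratum,metric,printed,tolerance
overall,sensitivity,72.7,0.05
overall,specificity,73.6,0.05
3+4,sensitivity,63.6,0.05
3+4,specificity,76,0.5
4+3,sensitivity,83.3,0.05
4+3,specificity,62.5,0.05
8-10,sensitivity,92.8,0.1
8-10,specificity,62.5,0.05
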