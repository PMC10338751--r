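# Default machine tolerances. The clinical alarm/abort thresholds of the
# vendor are proprietary; sites must override these with their own values.
pos_systematic_mm: 1.0
pos_random_mm: 1.0
size_percent: 10.0
mu_abs: 0.001
mu_min: 0.003
mu_max: 5.0
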