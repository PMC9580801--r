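# Study-level inflamed call counts under the three inflammation models.
model	n_inflamed	n_total
Infl1-tertile	163	264
Infl1-binary	95	264
Infl4	174	264
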