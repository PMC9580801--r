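# Swab-quality ledger: collected swabs and inclusion-gate failures.
phase	n_collected	n_failed
phase3	267	6
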