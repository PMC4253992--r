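haplotype	frequency_pct
ACAC	38.8
CCCC	30.8
ATAT	30.4
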