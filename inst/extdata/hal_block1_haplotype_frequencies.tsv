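haplotype	frequency_pct
TTTCGG	33.9
CCCCAG	24.8
CTTTGA	16.6
CTTCGA	9.4
CTTCGG	9.1
CTTTGG	3.0
CCTCAG	2.4
CCTCAA	0.07
CTTCAG	0.01
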