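set	rate	source
EMR	0.00069	evolutionary mutation rate, set-level average (Zhivotovsky et al. 2004)
OMRB	0.0021	observed genealogical rate, set-level average (Burgarella & Navascues 2011)
OMRS	0.0025	observed genealogical rate, set-level average (father-son pair surveys)
lmMR	0.0012	logistic-model-adjusted genealogical rate, set-level average (Burgarella & Navascues 2011)
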