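# Synthetic stand-in DE transcript list (14 genes; exactly CTSB, CHI3L1,
# MMP9, S100A8, S100A9 overlap the protein union).
CTSB
CHI3L1
MMP9
S100A8
S100A9
MMP12
CD68
CCL2
IL1B
CD36
PLAUR
CTSS
FCGR3A
TYROBP
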