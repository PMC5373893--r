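# Synthetic stand-in secretome hit list (lipid-loaded SMC conditioned media).
LGALS3BP
FN1
MMP9
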