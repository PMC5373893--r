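# Synthetic stand-in DE list for the GuHCl extraction fraction (14 proteins;
# CTHRC1 and APOA1 shared with the NaCl fraction).
CTHRC1
APOA1
COL1A1
COL1A2
COL3A1
COL4A1
FMOD
DCN
OGN
PRELP
ELN
EMILIN1
LTBP1
MGP
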