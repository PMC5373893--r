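# Synthetic stand-in DE list for the NaCl extraction fraction (18 proteins).
# Membership beyond the published constraints is illustrative.
MMP9
FN1
SPP1
LGALS3BP
CTHRC1
APOA1
CTSB
CHI3L1
S100A8
S100A9
TNC
THBS1
VCAN
BGN
LUM
SERPINA3
CLU
APOE
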