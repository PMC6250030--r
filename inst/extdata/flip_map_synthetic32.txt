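L01 R01
L02 R02
L03 R03
L04 R04
L05 R05
L06 R06
L07 R07
L08 R08
L09 R09
L10 R10
L11 R11
L12 R12
L13 R13
L14 R14
L15 R15
M01 M01
M02 M02
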