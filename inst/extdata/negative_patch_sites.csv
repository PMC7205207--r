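chain,position
L,49
L,50
L,51
L,52
L,53
L,96
H,52a
H,53
H,61
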