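name,formula,adducts
C8:0,C8H16O2,[M-H]-
C10:0,C10H20O2,[M-H]-
C12:0,C12H24O2,[M-H]-
C12:1,C12H22O2,[M-H]-
C14:0,C14H28O2,[M-H]-
C14:1,C14H26O2,[M-H]-
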