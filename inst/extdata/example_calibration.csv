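dosimeter_id,pulses
C1,980
C2,990
C3,1000
C4,1010
C5,1020
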