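protocol,dosimeter_id,pulses
P1,B1,45
P1,B2,50
P1,B3,55
P2,B1,48
P2,B2,50
P2,B3,52
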