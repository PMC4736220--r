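protocol,location,position,pulses
P1,thyroid_l,1,2050
P1,thyroid_l,2,2150
P1,thyroid_r,1,1950
P1,thyroid_r,2,2050
P1,mandible,1,1050
P1,mandible,2,1150
P1,calvarium,1,550
P1,calvarium,2,650
P2,thyroid_l,1,1650
P2,thyroid_l,2,1750
P2,thyroid_r,1,1550
P2,thyroid_r,2,1650
P2,mandible,1,850
P2,mandible,2,950
P2,calvarium,1,450
P2,calvarium,2,550
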