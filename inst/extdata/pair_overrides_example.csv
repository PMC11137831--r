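type_i,type_j,C12,C6,C4
M2p,o,300000,350,104.0
M2p,OW,280000,320,160.0
o,OW,585000,597,22.0
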