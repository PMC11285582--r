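# Two approved X-ray contrast agents, transcribed from their public
# structure records: iohexol (DB01362) and iodixanol (DB01249).
# Formulas check out as C19H26I3N3O9 and C35H44I6N6O15 respectively.
CC(=O)N(CC(O)CO)c1c(I)c(C(=O)NCC(O)CO)c(I)c(C(=O)NCC(O)CO)c1I DB01362
CC(=O)N(CC(O)CN(C(C)=O)c1c(I)c(C(=O)NCC(O)CO)c(I)c(C(=O)NCC(O)CO)c1I)c1c(I)c(C(=O)NCC(O)CO)c(I)c(C(=O)NCC(O)CO)c1I DB01249
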