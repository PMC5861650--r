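SMALL_INDEL: 0.17
DELETION: 0.4
INVERSION: 0.18
HOMOLOG_RR_g323.R_g323.R: 0.0075
WILDTYPE: 0.2425
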