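quantity	count
hsp_numts_total	766
hsp_numts_sequenced	339
assembled_numts_total	585
numts_fes_validated	558
numts_not_validated	27
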