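category	count
PCR and HapMap	5
PCR and Seq	26
PCR, Seq and HapMap	247
HapMap only	279
PCR only	1
Not validated	27
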