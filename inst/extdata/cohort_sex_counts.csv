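group,male,female
MCI,12,22
CN,6,28
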