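group,n_pairs,n_discordant
all,243,16
field_1.5T,81,10
field_3T,162,6
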