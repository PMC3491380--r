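quantity	count
coding_frameshift	705
coding_inframe	434
insertions_total	372604
deletions_total	596188
insertions_repeat	154649
deletions_repeat	250398
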