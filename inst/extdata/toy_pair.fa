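>toy_source
1 2 3 4 5 6 7 8
>toy_target
1 2 4 6 3 5 7 8
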