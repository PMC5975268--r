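# gene pairs framing intergenic regions of the derived genome
# (reading direction of the derived order)
trnQ nad2
cob nad1
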