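# maximal conserved gene runs shared by the two orders (one per line)
trnC trnY cox1 trnL2
trnK trnD atp8 atp6 cox3
trnG nad3 trnA
trnS1 trnE
trnF nad5 trnH nad4 nad4l trnT trnP nad6 cob
nad1 trnL1 rrnL trnV rrnS CR
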