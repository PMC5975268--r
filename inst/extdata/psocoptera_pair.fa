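# Prionoglaris stygia: ancestral Pancrustacea mitochondrial gene order
# (37 genes + control region CR).  Trogiomorpha_reconstructed: the derived
# order shared by Lepidopsocidae sp. and Dorypteryx domestica, reconstructed
# computationally as the unique single-TDRL image of the ancestral order
# whose maximal conserved segments match the six known shared segments
# (see the package vignette); it was not taken from a sequence database.
>Prionoglaris_stygia
cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE
trnF nad5 trnH nad4 nad4l trnT trnP nad6 cob trnS2 nad1 trnL1 rrnL trnV rrnS
CR trnI trnQ trnM nad2 trnW trnC trnY
>Trogiomorpha_reconstructed
trnC trnY cox1 trnL2 trnK trnD atp8 atp6 cox3 trnR trnS1 trnE trnS2 trnI trnM
trnW cox2 trnG nad3 trnA trnN trnF nad5 trnH nad4 nad4l trnT trnP nad6 cob
nad1 trnL1 rrnL trnV rrnS CR trnQ nad2
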