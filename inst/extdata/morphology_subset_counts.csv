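genotype,speed_class,n_cells
control,fast,70
control,moderate,40
control,slow,40
mutant,fast,49
mutant,moderate,40
mutant,slow,40
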