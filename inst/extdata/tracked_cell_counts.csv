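genotype,speed_class,n_cells,n_total
control,non_migratory,126,806
control,slow,355,806
control,moderate,186,806
control,fast,139,806
mutant,non_migratory,205,844
mutant,slow,430,844
mutant,moderate,139,844
mutant,fast,70,844
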