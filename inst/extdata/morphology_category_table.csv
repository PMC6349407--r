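genotype,slice,speed_class,category,n,n_total
control,1,fast,bipolar,15,27
control,2,fast,bipolar,12,26
control,3,fast,bipolar,7,17
control,1,fast,transitionary,12,27
control,2,fast,transitionary,13,26
control,3,fast,transitionary,10,17
control,1,fast,multipolar,0,27
control,2,fast,multipolar,1,26
control,3,fast,multipolar,0,17
control,1,moderate,bipolar,8,16
control,2,moderate,bipolar,4,10
control,3,moderate,bipolar,4,14
control,1,moderate,transitionary,7,16
control,2,moderate,transitionary,6,10
control,3,moderate,transitionary,10,14
control,1,moderate,multipolar,1,16
control,2,moderate,multipolar,0,10
control,3,moderate,multipolar,0,14
control,1,slow,bipolar,3,11
control,2,slow,bipolar,7,12
control,3,slow,bipolar,7,17
control,1,slow,transitionary,2,11
control,2,slow,transitionary,1,12
control,3,slow,transitionary,3,17
control,1,slow,multipolar,6,11
control,2,slow,multipolar,4,12
control,3,slow,multipolar,7,17
mutant,1,fast,bipolar,5,16
mutant,2,fast,bipolar,6,15
mutant,3,fast,bipolar,5,18
mutant,1,fast,transitionary,9,16
mutant,2,fast,transitionary,8,15
mutant,3,fast,transitionary,12,18
mutant,1,fast,multipolar,2,16
mutant,2,fast,multipolar,1,15
mutant,3,fast,multipolar,1,18
mutant,1,moderate,bipolar,4,13
mutant,2,moderate,bipolar,5,19
mutant,3,moderate,bipolar,5,8
mutant,1,moderate,transitionary,9,13
mutant,2,moderate,transitionary,14,19
mutant,3,moderate,transitionary,3,8
mutant,1,moderate,multipolar,0,13
mutant,2,moderate,multipolar,0,19
mutant,3,moderate,multipolar,0,8
mutant,1,slow,bipolar,5,14
mutant,2,slow,bipolar,5,15
mutant,3,slow,bipolar,2,11
mutant,1,slow,transitionary,5,14
mutant,2,slow,transitionary,5,15
mutant,3,slow,transitionary,5,11
mutant,1,slow,multipolar,4,14
mutant,2,slow,multipolar,5,15
mutant,3,slow,multipolar,4,11
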