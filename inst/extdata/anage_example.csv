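# AnAge-style species characteristics, years; approximate published values
# for a selection of well-studied mammals. species_id matches the default
# exempt set for lifespan adjustment (human, house mouse).
species_id,max_lifespan,gestation_time,asm
human,122.5,0.75,13.5
house mouse,4,0.052,0.13
bowhead whale,211,1.08,20
brown rat,3.8,0.06,0.25
dog,24,0.17,0.65
domestic cattle,20,0.78,1.5
horse,57,0.93,2.5
african elephant,65.5,1.8,11
naked mole rat,37,0.19,0.75
bottlenose dolphin,51.6,1.03,8
rhesus macaque,40,0.46,4
european rabbit,18,0.085,0.5
little brown bat,34,0.16,0.6
wild boar,27,0.31,0.55
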