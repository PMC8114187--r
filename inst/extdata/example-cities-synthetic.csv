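country,city,population
U0001,U0001_city1,2559888
U0001,U0001_city2,2231564
U0001,U0001_city3,866017
U0002,U0002_city1,3822658
U0002,U0002_city2,1353337
U0002,U0002_city3,3548413
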