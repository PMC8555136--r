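taxon	state
Chrysomyinae	1
Phumosiinae	1
Ameniinae	1
Helicoboscinae	0
Rhinophoridae	0
Rhiniidae	1
Bengaliinae	1
Luciliinae	1
Calliphorinae	1
Toxotarsinae	1
Outgroup	0
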