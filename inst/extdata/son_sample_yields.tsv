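condition	sample	yield	rin
Normosmotic	HGN01	300	7.2
Normosmotic	HGN02	274	6.6
Normosmotic	HGN03	386	7.0
Salt-Loaded	HGSL01	658	7.6
Salt-Loaded	HGSL02	552	7.2
Salt-Loaded	HGSL03	748	7.2
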