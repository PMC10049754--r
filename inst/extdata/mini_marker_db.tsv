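species	tissue	cell_type	gene
human	Peripheral blood	B cell	930
human	Peripheral blood	B cell	931
human	Peripheral blood	B cell	933
human	Blood	B cell	930
human	Blood	B cell	974
human	Blood	T cell	915
human	Blood	T cell	916
human	Peripheral blood	T cell	920
human	Peripheral blood	T cell	925
human	Umbilical cord blood	Monocyte	929
human	Blood	Monocyte	1436
human	Blood	Monocyte	2322
human	Brain	Astrocyte	2670
human	Brain	Astrocyte	2596
human	Embryonic brain	Neuron	4744
human	Brain	Neuron	4747
mouse	Blood	B cell	12478
mouse	Blood	T cell	12501
mouse	Brain	Astrocyte	14580
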