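genus	taxon	genome_size_pg
Populus	angiosperm	0.52
Eucalyptus	angiosperm	0.60
Betula	angiosperm	0.62
Fagus	angiosperm	0.56
Quercus	angiosperm	0.87
Citrus	angiosperm	0.44
Prunus	angiosperm	0.57
Fraxinus	angiosperm	0.93
Picea	gymnosperm	18.1
Pinus	gymnosperm	26.4
Cryptomeria	gymnosperm	11.2
Gnetum	gymnosperm	3.4
Cycas	gymnosperm	14.7
Zamia	gymnosperm	17.0
Ginkgo	gymnosperm	11.8
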