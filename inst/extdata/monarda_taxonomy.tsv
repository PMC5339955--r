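genus	order	class	phylum
Alternaria	Pleosporales	Dothideomycetes	Ascomycota
Aspergillus	Eurotiales	Eurotiomycetes	Ascomycota
Cladosporium	Capnodiales	Dothideomycetes	Ascomycota
Colletotrichum	Glomerellales	Sordariomycetes	Ascomycota
Curvularia	Pleosporales	Dothideomycetes	Ascomycota
Fusarium	Hypocreales	Sordariomycetes	Ascomycota
Gibberella	Hypocreales	Sordariomycetes	Ascomycota
Muscodor	Xylariales	Sordariomycetes	Ascomycota
Neosartorya	Eurotiales	Eurotiomycetes	Ascomycota
Neurospora	Sordariales	Sordariomycetes	Ascomycota
Penicillium	Eurotiales	Eurotiomycetes	Ascomycota
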