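prey_taxon,class
Insecta,Insecta
Arachnida,Arachnida
Malacostraca,Malacostraca
Diplopoda,Diplopoda
Chilopoda,Chilopoda
Gastropoda,Gastropoda
Opisthopora,Opisthopora
Osteichthyes,Osteichthyes
Amphibia,Amphibia
Squamata,Squamata
Aves,Aves
Mammalia,Mammalia
Coleoptera,Insecta
Diptera,Insecta
Lepidoptera,Insecta
Orthoptera,Insecta
Blattodea,Insecta
Hymenoptera,Insecta
Hemiptera,Insecta
Dermaptera,Insecta
Araneae,Arachnida
Opiliones,Arachnida
Scorpiones,Arachnida
Isopoda,Malacostraca
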