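((((Helix_aspersa:400,Arion_vulgaris:400)Gastropoda:150,(Lumbricus_terrestris:200,Eisenia_fetida:200)Opisthopora:350)Lophotrochozoa:70,((Araneae_sp:500,Scorpiones_sp:500)Arachnida:70,(((Scolopendra_morsitans:300,Lithobius_forficatus:300)Chilopoda:180,(Julus_scandinavius:300,Polydesmus_angustus:300)Diplopoda:180)Myriapoda:60,((Porcellio_scaber:350,Oniscus_asellus:350)Malacostraca:150,((Musca_domestica:300,(Galleria_mellonella:250,Apis_mellifera:250)Endopterygota:50)Holometabola:100,(Periplaneta_americana:350,Acheta_domesticus:350)Polyneoptera:50)Insecta:100)Pancrustacea:40)Mandibulata:30)Arthropoda:50)Protostomia:80,((Danio_rerio:250,Gasterosteus_aculeatus:250)Osteichthyes:180,((Xenopus_laevis:250,Rana_temporaria:250)Amphibia:100,((Mus_musculus:20,Rattus_norvegicus:20)Mammalia:300,((Anolis_carolinensis:170,Natrix_natrix:170)Squamata:110,(Gallus_gallus:100,Taeniopygia_guttata:100)Aves:180)Sauropsida:40)Amniota:30)Tetrapoda:80)Vertebrata:270)Bilateria;
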