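crop_label,genera,included_species,excluded_species
Rice,Oryza,,
Wheat,Triticum;Agropyron;Elymus;Triticale,,
Barley,Hordeum,,
Maize,Zea,,perennis;diploperennis;luxurians
Sorghum,Sorghum,,
Oat,Avena,,
Pearl millet,Pennisetum,,
Finger millet,Eleusine,,
Rye,Secale,,
Bean,Phaseolus,,polyanthus
Cowpea,Vigna,,
Chickpea,Cicer,,
Pea,Pisum,,
Faba bean and vetch,Vicia,,
Lentil,Lens,culinaris,
Pigeon pea,Cajanus,,
Potato,Solanum,,phureja
Sweet potato,Ipomoea,,
Brassica complex,Brassica;Armoracia;Barbarea;Camelina;Crambe;Diplotaxis;Eruca;Isatis;Lepidium;Raphanobrassica;Raphanus;Rorippa;Sinapis,,
Sunflower,Helianthus,,
Alfalfa,Medicago,arborea;falcata;sativa;scutellata;rigidula;truncatula,
Clover,Trifolium,alexandrinum;alpestre;ambiguum;angustifolium;arvense;hybridum;incarnatum;pratense;repens;resupinatum;rueppellianum;semipilosum;subterraneum;vesiculosum,
Cassava,Manihot,esculenta,
Breadfruit,Artocarpus,altilis,
Asparagus,Asparagus,,
Beet,Beta,,
Citrus rootstock,Poncirus,,
Eggplant,Solanum,melongena,
Yam,Dioscorea,,
Banana and plantain,Musa,,textilis
Apple,Malus,,
Strawberry,Fragaria,,
Grass pea,Lathyrus,,
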