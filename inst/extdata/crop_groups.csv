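genus,crop_group
Triticum,Cereals
Oryza,Cereals
Hordeum,Cereals
Zea,Cereals
Sorghum,Cereals
Avena,Cereals
Pennisetum,Cereals
Setaria,Cereals
Aegilops,Cereals
Triticale,Cereals
Eleusine,Cereals
Amaranthus,Cereals
Secale,Cereals
Chenopodium,Cereals
Eragrostis,Cereals
Phaseolus,Food Legumes
Glycine,Food Legumes
Vigna,Food Legumes
Arachis,Food Legumes
Cicer,Food Legumes
Pisum,Food Legumes
Vicia,Food Legumes
Lens,Food Legumes
Cajanus,Food Legumes
Lupinus,Food Legumes
Psophocarpus,Food Legumes
Lathyrus,Food Legumes
Medicago,Forage Crops
Trifolium,Forage Crops
Panicum,Forage Crops
Festuca,Forage Crops
Dactylis,Forage Crops
Lolium,Forage Crops
Phleum,Forage Crops
Bromus,Forage Crops
Solanum,Roots and Tubers
Ipomoea,Roots and Tubers
Manihot,Roots and Tubers
Dioscorea,Roots and Tubers
Colocasia,Roots and Tubers
Ullucus,Roots and Tubers
Brassica,Vegetables
Capsicum,Vegetables
Lycopersicon,Vegetables
Cucumis,Vegetables
Cucurbita,Vegetables
Allium,Vegetables
Abelmoschus,Vegetables
Asparagus,Vegetables
Raphanus,Vegetables
Sesamum,Oil Crops
Helianthus,Oil Crops
Carthamus,Oil Crops
Gossypium,Fibre Crops
Linum,Fibre Crops
Saccharum,Sugar Crops
Beta,Sugar Crops
Malus,Fruits and Nuts
Prunus,Fruits and Nuts
Vitis,Fruits and Nuts
Citrus,Fruits and Nuts
Musa,Fruits and Nuts
Fragaria,Fruits and Nuts
Coffea,Other
Theobroma,Other
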