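genus,status,provenance
Arabidopsis,excluded_non_pgrfa,printed
Picea,excluded_non_pgrfa,printed
Pinus,excluded_non_pgrfa,printed
Populus,excluded_non_pgrfa,printed
Pseudotsuga,excluded_non_pgrfa,printed
Rhododendron,excluded_non_pgrfa,printed
Amygdalis,excluded_not_in_sgsv,printed
Anacardium,excluded_not_in_sgsv,printed
Ananas,excluded_not_in_sgsv,printed
Annona,excluded_not_in_sgsv,printed
Bohemeria,excluded_not_in_sgsv,printed
Carya,excluded_not_in_sgsv,printed
Colocasia,excluded_not_in_sgsv,printed
Dioscorea,excluded_not_in_sgsv,printed
Ficus,excluded_not_in_sgsv,printed
Gladiolus,excluded_not_in_sgsv,printed
Ilex,excluded_not_in_sgsv,printed
Jathropha,excluded_not_in_sgsv,printed
Juglans,excluded_not_in_sgsv,printed
Malus,excluded_not_in_sgsv,printed
Manihot,excluded_not_in_sgsv,printed
Morus,excluded_not_in_sgsv,printed
Opuntia,excluded_not_in_sgsv,printed
Oxalis,excluded_not_in_sgsv,printed
Phoenix,excluded_not_in_sgsv,printed
Pistacia,excluded_not_in_sgsv,printed
Prunus,excluded_not_in_sgsv,printed
Punica,excluded_not_in_sgsv,printed
Tulipa,excluded_not_in_sgsv,printed
Ullucus,excluded_not_in_sgsv,printed
Vitis,excluded_not_in_sgsv,printed
Zingiber,excluded_not_in_sgsv,printed
Bactris,excluded_not_in_sgsv_seed_behavior,printed
Camellia,excluded_not_in_sgsv_seed_behavior,printed
Carica,excluded_not_in_sgsv_seed_behavior,printed
Castanea,excluded_not_in_sgsv_seed_behavior,printed
Cinnamonum,excluded_not_in_sgsv_seed_behavior,printed
Citrus,excluded_not_in_sgsv_seed_behavior,printed
Cocos,excluded_not_in_sgsv_seed_behavior,printed
Coffea,excluded_not_in_sgsv_seed_behavior,printed
Corylus,excluded_not_in_sgsv_seed_behavior,printed
Curcuma,excluded_not_in_sgsv_seed_behavior,printed
Durio,excluded_not_in_sgsv_seed_behavior,printed
Elaeis,excluded_not_in_sgsv_seed_behavior,printed
Garcinia,excluded_not_in_sgsv_seed_behavior,printed
Hevea,excluded_not_in_sgsv_seed_behavior,printed
Mangifera,excluded_not_in_sgsv_seed_behavior,printed
Musa,excluded_not_in_sgsv_seed_behavior,printed
Nephelium,excluded_not_in_sgsv_seed_behavior,printed
Persea,excluded_not_in_sgsv_seed_behavior,printed
Piper,excluded_not_in_sgsv_seed_behavior,printed
Poncirus,excluded_not_in_sgsv_seed_behavior,printed
Pouteria,excluded_not_in_sgsv_seed_behavior,printed
Quercus,excluded_not_in_sgsv_seed_behavior,printed
Salix,excluded_not_in_sgsv_seed_behavior,printed
Theobroma,excluded_not_in_sgsv_seed_behavior,printed
Triticum,retained,printed
Oryza,retained,printed
Hordeum,retained,printed
Zea,retained,printed
Sorghum,retained,printed
Avena,retained,printed
Pennisetum,retained,printed
Setaria,retained,printed
Aegilops,retained,printed
Triticale,retained,printed
Eleusine,retained,printed
Amaranthus,retained,printed
Secale,retained,printed
Chenopodium,retained,printed
Eragrostis,retained,printed
Phaseolus,retained,printed
Glycine,retained,printed
Vigna,retained,printed
Arachis,retained,printed
Cicer,retained,printed
Pisum,retained,printed
Vicia,retained,printed
Lens,retained,printed
Cajanus,retained,printed
Lupinus,retained,printed
Psophocarpus,retained,printed
Medicago,retained,printed
Trifolium,retained,printed
Panicum,retained,printed
Solanum,retained,printed
Ipomoea,retained,printed
Brassica,retained,printed
Capsicum,retained,printed
Lycopersicon,retained,printed
Cucumis,retained,printed
Cucurbita,retained,printed
Allium,retained,printed
Sesamum,retained,printed
Helianthus,retained,printed
Carthamus,retained,printed
Abelmoschus,retained,printed
Gossypium,retained,printed
Linum,retained,printed
Saccharum,retained,printed
Festuca,retained,printed
Dactylis,retained,printed
Synthgenus001,retained,synthetic
Synthgenus002,retained,synthetic
Synthgenus003,retained,synthetic
Synthgenus004,retained,synthetic
Synthgenus005,retained,synthetic
Synthgenus006,retained,synthetic
Synthgenus007,retained,synthetic
Synthgenus008,retained,synthetic
Synthgenus009,retained,synthetic
Synthgenus010,retained,synthetic
Synthgenus011,retained,synthetic
Synthgenus012,retained,synthetic
Synthgenus013,retained,synthetic
Synthgenus014,retained,synthetic
Synthgenus015,retained,synthetic
Synthgenus016,retained,synthetic
Synthgenus017,retained,synthetic
Synthgenus018,retained,synthetic
Synthgenus019,retained,synthetic
Synthgenus020,retained,synthetic
Synthgenus021,retained,synthetic
Synthgenus022,retained,synthetic
Synthgenus023,retained,synthetic
Synthgenus024,retained,synthetic
Synthgenus025,retained,synthetic
Synthgenus026,retained,synthetic
Synthgenus027,retained,synthetic
Synthgenus028,retained,synthetic
Synthgenus029,retained,synthetic
Synthgenus030,retained,synthetic
Synthgenus031,retained,synthetic
Synthgenus032,retained,synthetic
Synthgenus033,retained,synthetic
Synthgenus034,retained,synthetic
Synthgenus035,retained,synthetic
Synthgenus036,retained,synthetic
Synthgenus037,retained,synthetic
Synthgenus038,retained,synthetic
Synthgenus039,retained,synthetic
Synthgenus040,retained,synthetic
Synthgenus041,retained,synthetic
Synthgenus042,retained,synthetic
Synthgenus043,retained,synthetic
Synthgenus044,retained,synthetic
Synthgenus045,retained,synthetic
Synthgenus046,retained,synthetic
Synthgenus047,retained,synthetic
Synthgenus048,retained,synthetic
Synthgenus049,retained,synthetic
Synthgenus050,retained,synthetic
Synthgenus051,retained,synthetic
Synthgenus052,retained,synthetic
Synthgenus053,retained,synthetic
Synthgenus054,retained,synthetic
Synthgenus055,retained,synthetic
Synthgenus056,retained,synthetic
Synthgenus057,retained,synthetic
Synthgenus058,retained,synthetic
Synthgenus059,retained,synthetic
Synthgenus060,retained,synthetic
Synthgenus061,retained,synthetic
Synthgenus062,retained,synthetic
Synthgenus063,retained,synthetic
Synthgenus064,retained,synthetic
Synthgenus065,retained,synthetic
Synthgenus066,retained,synthetic
Synthgenus067,retained,synthetic
Synthgenus068,retained,synthetic
Synthgenus069,retained,synthetic
Synthgenus070,retained,synthetic
Synthgenus071,retained,synthetic
Synthgenus072,retained,synthetic
Synthgenus073,retained,synthetic
Synthgenus074,retained,synthetic
Synthgenus075,retained,synthetic
Synthgenus076,retained,synthetic
Synthgenus077,retained,synthetic
Synthgenus078,retained,synthetic
Synthgenus079,retained,synthetic
Synthgenus080,retained,synthetic
Synthgenus081,retained,synthetic
Synthgenus082,retained,synthetic
Synthgenus083,retained,synthetic
Synthgenus084,retained,synthetic
Synthgenus085,retained,synthetic
Synthgenus086,retained,synthetic
Synthgenus087,retained,synthetic
Synthgenus088,retained,synthetic
Synthgenus089,retained,synthetic
Synthgenus090,retained,synthetic
Synthgenus091,retained,synthetic
Synthgenus092,retained,synthetic
Synthgenus093,retained,synthetic
Synthgenus094,retained,synthetic
Synthgenus095,retained,synthetic
Synthgenus096,retained,synthetic
Synthgenus097,retained,synthetic
Synthgenus098,retained,synthetic
Synthgenus099,retained,synthetic
Synthgenus100,retained,synthetic
Synthgenus101,retained,synthetic
Synthgenus102,retained,synthetic
Synthgenus103,retained,synthetic
Synthgenus104,retained,synthetic
Synthgenus105,retained,synthetic
Synthgenus106,retained,synthetic
Synthgenus107,retained,synthetic
Synthgenus108,retained,synthetic
Synthgenus109,retained,synthetic
Synthgenus110,retained,synthetic
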