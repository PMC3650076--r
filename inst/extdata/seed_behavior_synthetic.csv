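genus,species_epithet,behavior
Triticum,aestivum,orthodox
Triticum,durum,orthodox
Triticum,monococcum,orthodox
Oryza,sativa,orthodox
Oryza,glaberrima,orthodox
Hordeum,vulgare,orthodox
Zea,mays,orthodox
Phaseolus,vulgaris,orthodox
Phaseolus,lunatus,orthodox
Glycine,max,orthodox
Citrus,sinensis,intermediate
Citrus,limon,intermediate
Citrus,reticulata,intermediate
Coffea,arabica,intermediate
Coffea,canephora,intermediate
Coffea,liberica,intermediate
Quercus,robur,recalcitrant
Quercus,alba,recalcitrant
Theobroma,cacao,recalcitrant
Cocos,nucifera,recalcitrant
Castanea,sativa,recalcitrant
Mangifera,indica,recalcitrant
Persea,americana,recalcitrant
Camellia,sinensis,recalcitrant
Camellia,japonica,intermediate
Elaeis,guineensis,intermediate
Hevea,brasiliensis,recalcitrant
Musa,acuminata,intermediate
Musa,balbisiana,orthodox
Carica,papaya,intermediate
Solanum,tuberosum,orthodox
Solanum,melongena,orthodox
Solanum,lycopersicum,orthodox
Ipomoea,batatas,orthodox
Allium,cepa,orthodox
Allium,sativum,orthodox
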