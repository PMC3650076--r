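genus,n_in_sgsv,n_under_sda,bracket_consistent
Oryza,4,5,TRUE
Triticum,5,7,TRUE
Hordeum,6,7,TRUE
Sorghum,4,7,TRUE
Zea,3,5,TRUE
Glycine,4,6,FALSE
Phaseolus,5,6,FALSE
Vigna,4,7,TRUE
Avena,5,7,FALSE
Arachis,2,3,TRUE
Cicer,6,7,FALSE
Solanum,5,6,TRUE
Pennisetum,3,4,FALSE
Brassica,2,3,FALSE
Vicia,5,5,FALSE
Pisum,5,6,TRUE
Setaria,4,5,FALSE
Lens,5,7,FALSE
Cajanus,3,7,TRUE
Capsicum,3,5,FALSE
Sesamum,1,5,FALSE
Eleusine,4,5,TRUE
Triticale,5,6,FALSE
Cucumis,3,5,FALSE
Helianthus,2,5,FALSE
Lupinus,3,4,FALSE
Ipomoea,3,3,FALSE
Allium,3,5,FALSE
Amaranthus,2,6,TRUE
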