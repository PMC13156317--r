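taxon,threatened,non_native
Festuca_rubra,FALSE,FALSE
Poa_pratensis,FALSE,FALSE
Trifolium_repens,FALSE,FALSE
Achillea_millefolium,FALSE,FALSE
Solidago_canadensis,FALSE,TRUE
Vaccinium_myrtillus,FALSE,FALSE
Betula_pendula,FALSE,FALSE
Picea_abies,FALSE,FALSE
Carex_rostrata,TRUE,FALSE
Sphagnum_fallax,TRUE,FALSE
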