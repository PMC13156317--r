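taxon,height_m,sla_mm2_mg,seed_mass_mg
Festuca_rubra,0.6,18.2,0.95
Poa_pratensis,0.7,24.1,0.30
Trifolium_repens,0.2,22.5,0.65
Achillea_millefolium,0.5,15.8,0.15
Solidago_canadensis,1.2,14.9,0.06
Vaccinium_myrtillus,0.3,13.1,0.25
Betula_pendula,22.0,12.4,0.17
Picea_abies,35.0,4.6,7.10
Carex_rostrata,0.8,16.3,0.85
Sphagnum_fallax,0.05,30.0,0.01
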