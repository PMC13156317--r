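(Sphagnum_fallax:4,((Picea_abies:2.5,Betula_pendula:2.5):1,(((Festuca_rubra:0.8,Poa_pratensis:0.8):0.7,Carex_rostrata:1.5):1,((Trifolium_repens:1.2,(Achillea_millefolium:0.9,Solidago_canadensis:0.9):0.3):0.6,Vaccinium_myrtillus:1.8):0.7):1):0.5);
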