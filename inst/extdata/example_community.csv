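obs_id,series_id,plot_id,year,plot_size,taxon,layer,cover,eunis_l1,eunis_l3,design,manipulated
g1_1990,g1,g1,1990,16,Festuca_rubra,herb,45,R,R22,permanent,FALSE
g1_1990,g1,g1,1990,16,Poa_pratensis,herb,30,R,R22,permanent,FALSE
g1_1990,g1,g1,1990,16,Trifolium_repens,herb,15,R,R22,permanent,FALSE
g1_2005,g1,g1,2005,16,Festuca_rubra,herb,40,R,R22,permanent,FALSE
g1_2005,g1,g1,2005,16,Poa_pratensis,herb,25,R,R22,permanent,FALSE
g1_2005,g1,g1,2005,16,Trifolium_repens,herb,20,R,R22,permanent,FALSE
g1_2005,g1,g1,2005,16,Achillea_millefolium,herb,10,R,R22,permanent,FALSE
g1_2020,g1,g1,2020,16,Festuca_rubra,herb,35,R,R22,permanent,FALSE
g1_2020,g1,g1,2020,16,Poa_pratensis,herb,20,R,R22,permanent,FALSE
g1_2020,g1,g1,2020,16,Trifolium_repens,herb,20,R,R22,permanent,FALSE
g1_2020,g1,g1,2020,16,Achillea_millefolium,herb,15,R,R22,permanent,FALSE
g1_2020,g1,g1,2020,16,Solidago_canadensis,herb,10,R,R22,permanent,FALSE
s1_1995,s1,s1,1995,50,Festuca_rubra,herb,40,R,R22,semi_permanent,FALSE
s1_1995,s1,s1,1995,50,Achillea_millefolium,herb,20,R,R22,semi_permanent,FALSE
s1_1995,s1,s1,1995,50,Vaccinium_myrtillus,herb,10,R,R22,semi_permanent,FALSE
s1_2010,s1,s1,2010,50,Vaccinium_myrtillus,herb,30,S,S42,semi_permanent,FALSE
s1_2010,s1,s1,2010,50,Betula_pendula,shrub,25,S,S42,semi_permanent,FALSE
s1_2010,s1,s1,2010,50,Festuca_rubra,herb,15,S,S42,semi_permanent,FALSE
s1_2022,s1,s1,2022,50,Betula_pendula,tree,45,T,T18,semi_permanent,FALSE
s1_2022,s1,s1,2022,50,Betula_pendula,shrub,15,T,T18,semi_permanent,FALSE
s1_2022,s1,s1,2022,50,Picea_abies,tree,20,T,T18,semi_permanent,FALSE
s1_2022,s1,s1,2022,50,Vaccinium_myrtillus,herb,25,T,T18,semi_permanent,FALSE
m1_1985,m1,m1,1985,25,Carex_rostrata,herb,50,Q,Q22,permanent,FALSE
m1_1985,m1,m1,1985,25,Sphagnum_fallax,herb,60,Q,Q22,permanent,FALSE
m1_2015,m1,m1,2015,25,Carex_rostrata,herb,45,Q,Q22,permanent,FALSE
m1_2015,m1,m1,2015,25,Sphagnum_fallax,herb,55,Q,Q22,permanent,FALSE
m1_2015,m1,m1,2015,25,Betula_pendula,shrub,5,Q,Q22,permanent,FALSE
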