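species,site_id,sla,mat,map,tn,ph,clade,phenology,woody
Pinus_synthetica,S01,85.2,4.5,620,1.2,5.8,gymnosperm,evergreen,TRUE
Pinus_synthetica,S02,92.7,8.1,840,1.6,6.1,gymnosperm,evergreen,TRUE
Larix_ficta,S03,148.9,-2.3,450,0.9,5.2,gymnosperm,deciduous,TRUE
Quercus_simulata,S01,176.4,4.5,620,1.2,5.8,eudicot,deciduous,TRUE
Quercus_simulata,S04,201.8,12.6,1150,2.1,6.7,eudicot,deciduous,TRUE
Acer_fictum,S02,223.5,8.1,840,,6.1,eudicot,deciduous,TRUE
Betula_exemplaris,S03,254.1,-2.3,450,0.9,5.2,eudicot,deciduous,TRUE
Poa_exempli,S04,312.6,12.6,1150,2.1,6.7,monocot,deciduous,FALSE
Carex_simulata,S05,287.3,15.2,1480,,7.2,monocot,evergreen,FALSE
Rosa_ficta,S05,198.4,15.2,1480,2.8,7.2,eudicot,deciduous,TRUE
Salix_demo,S03,244.9,-2.3,450,0.9,5.2,eudicot,deciduous,TRUE
Artemisia_mock,S04,167.2,12.6,1150,2.1,6.7,eudicot,deciduous,FALSE
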