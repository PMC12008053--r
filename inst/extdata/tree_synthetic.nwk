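((Pinus_synthetica:80,(Larix_ficta:60,Ginkgo_extra:60):20):240,((Poa_exempli:120,Carex_simulata:120):120,((Quercus_simulata:90,(Betula_exemplaris:70,Fagus_extra:70):20):60,(Acer_fictum:120,Rosa_ficta:120):30):90):80);
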