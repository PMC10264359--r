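species,age_maturity,repro_mode,trophic_level
scyliorhinus_canicula,5.0,oviparous,3.60
raja_miraletus,2.5,oviparous,3.67
squalus_acanthias,15.0,viviparous,3.90
raja_clavata,7.5,oviparous,3.69
mustelus_spp,10.5,viviparous,3.80
myliobatis_aquila,3.0,viviparous,3.33
torpedo_marmorata,12.0,viviparous,4.24
raja_asterias,3.5,oviparous,3.82
scyliorhinus_stellaris,5.0,oviparous,4.00
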