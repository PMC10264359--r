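species,phylum,class,order,family,genus,species_name
scyliorhinus_canicula,Chordata,Chondrichthyes,Carcharhiniformes,Scyliorhinidae,Scyliorhinus,Scyliorhinus_canicula
raja_miraletus,Chordata,Chondrichthyes,Rajiformes,Rajidae,Raja,Raja_miraletus
squalus_acanthias,Chordata,Chondrichthyes,Squaliformes,Squalidae,Squalus,Squalus_acanthias
raja_clavata,Chordata,Chondrichthyes,Rajiformes,Rajidae,Raja,Raja_clavata
mustelus_spp,Chordata,Chondrichthyes,Carcharhiniformes,Triakidae,Mustelus,Mustelus_spp
myliobatis_aquila,Chordata,Chondrichthyes,Myliobatiformes,Myliobatidae,Myliobatis,Myliobatis_aquila
torpedo_marmorata,Chordata,Chondrichthyes,Torpediniformes,Torpedinidae,Torpedo,Torpedo_marmorata
raja_asterias,Chordata,Chondrichthyes,Rajiformes,Rajidae,Raja,Raja_asterias
scyliorhinus_stellaris,Chordata,Chondrichthyes,Carcharhiniformes,Scyliorhinidae,Scyliorhinus,Scyliorhinus_stellaris
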