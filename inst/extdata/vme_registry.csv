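taxon,rank,group,parent,NPFC,SPRFMO,NEAFC,NAFO_ABNJ,CCAMLR,SEAFO,GFCM,SIOFA
Actiniaria,order,Cnidaria,,no,yes,no,no,yes,no,no,yes
Ceriantharia,subclass,Cnidaria,,no,no,qualified:only Cerianthidae,qualified:only Cerianthidae,no,qualified:only Cerianthidae,yes,no
Alcyonacea,order,Cnidaria,,qualified:as Alcyonacea & Gorgonacea,qualified:as Gorgonian Alcyonacea (Holaxonia; Calcaxonia; Scleraxonia) & Alcyonacea excluding gorgonians,yes,qualified:as Gorgonian Alcyonacea suborders Holaxonia; Calcaxonia; Scleraxonia,qualified:as Alcyonacea & Gorgonacea,qualified:as Alcyonacea & Gorgonacea,yes,qualified:as Alcyonacea & Gorgonacea
Pennatulacea,order,Cnidaria,,no,yes,yes,yes,yes,yes,yes,yes
Antipatharia,order,Cnidaria,,yes,yes,qualified:Schizopathidae; Leiopathidae; Antipathidae,yes,yes,yes,yes,yes
Scleractinia,order,Cnidaria,,yes,qualified:as five genera Solenosmilia; Goniocorella; Oculina; Enallopsammia; Madrepora; Lophelia,yes,qualified:four branching spp. Enallopsammia rostrata; Lophelia pertusa; Madrepora oculata; Solenosmilia variabilis,yes,yes,yes,yes
Hydroidolina,subclass,Cnidaria,,no,qualified:as the orders Anthoathecata & Leptothecata,no,no,yes,qualified:only Anthoathecata,yes,qualified:only Anthoathecata
Stylasteridae,family,Cnidaria,Hydroidolina,no,yes,yes,no,yes,no,qualified!:as subclass Hydroidolina,yes
Zoantharia,order,Cnidaria,,no,yes,no,no,yes,yes,no,yes
Brisingida,order,Echinodermata,,no,yes,no,no,no,no,no,no
Crinoidea,class,Echinodermata,,no,yes,qualified:stalked only,qualified:stalked only,qualified:stalked only,yes,yes,qualified:stalked only
Echinoidea,class,Echinodermata,,no,no,no,no,qualified:as Cidaroida,no,no,qualified:as Cidaroida
Ophiuroidea,class,Echinodermata,,no,no,no,no,qualified:as Euryalida,qualified:as basket stars,no,qualified:as Euryalida
Arthropoda,phylum,OtherTaxa,,no,no,qualified:chemosynthetic ecosystem decapods only,no,qualified:Bathylasmatidae,no,no,qualified:Bathylasmatidae
Ascidiacea,class,OtherTaxa,,no,no,no,yes,yes,yes,no,yes
Bivalvia,class,OtherTaxa,,no,no,qualified:chemosynthetic communities,no,qualified:as Adamussium colbecki,no,qualified:chemosynthetic communities & Gryphaeidae,no
Brachiopoda,phylum,OtherTaxa,,no,no,no,no,yes,no,no,yes
Bryozoa,phylum,OtherTaxa,,no,qualified:all taxa within the orders Cheilostomatida & Ctenostomatida,qualified:only Eucratea loricata,qualified:fenestrate taxa,yes,yes,qualified:only Gymnolaemata & Stenolaemata,yes
Polychaeta,class,OtherTaxa,,no,no,qualified:chemosynthetic communities,no,qualified:as Serpulidae,qualified:as Serpulidae,qualified:chemosynthetic communities; infraclass Canalipalpata,qualified:as Serpulidae
Porifera,phylum,OtherTaxa,,no,qualified:as classes Demospongiae & Hexactinellida,yes,yes,qualified:as Hexactinellida & Demospongiae,yes,qualified:Demospongiae & subclasses Amphidiscophora & Hexasterophora within Hexactinellida,qualified:as Hexactinellida & Demospongiae
Pterobranchia,class,OtherTaxa,,no,no,no,no,yes,no,no,yes
Xenophyophoroidea,suborder,OtherTaxa,,no,no,yes,yes,yes,no,no,yes
Chemosynthetic taxa,feature,Feature,,no,no,qualified:0-2000 m,no,yes,no,yes,yes
Seamounts as a whole,feature,Feature,,no,no,qualified:VME element,yes,no,no,qualified:VME-indicator feature,no
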