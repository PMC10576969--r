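alias,canonical
Gorgonacea,Alcyonacea
Gorgonian Alcyonacea,Alcyonacea
Crinoida,Crinoidea
Cerianthidae,Ceriantharia
Hexactinellida,Porifera
Demospongiae,Porifera
Cidaroida,Echinoidea
Euryalida,Ophiuroidea
Serpulidae,Polychaeta
Anthoathecata,Hydroidolina
Leptothecata,Hydroidolina
Xenophyophorea,Xenophyophoroidea
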