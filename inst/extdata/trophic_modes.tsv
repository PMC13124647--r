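class	mode
Chlorophyceae	phototroph
Trebouxiophyceae	phototroph
Mamiellophyceae	phototroph
Pyramimonadophyceae	phototroph
Bacillariophyceae	phototroph
Mediophyceae	phototroph
Coscinodiscophyceae	phototroph
Eustigmatophyceae	phototroph
Xanthophyceae	phototroph
Bolidophyceae	phototroph
Cryptophyceae	mixotroph
Chrysophyceae	mixotroph
Dinophyceae	mixotroph
Prymnesiophyceae	mixotroph
Euglenophyceae	mixotroph
Raphidophyceae	mixotroph
Chlorarachniophyceae	mixotroph
Spirotrichea	phagotroph
Oligohymenophorea	phagotroph
Litostomatea	phagotroph
Colpodea	phagotroph
Prostomatea	phagotroph
Nassophorea	phagotroph
Heterotrichea	phagotroph
Choanoflagellatea	phagotroph
Kinetoplastea	phagotroph
Bicoecea	phagotroph
Heterolobosea	phagotroph
Tubulinea	phagotroph
Filosa-Imbricatea	phagotroph
Filosa-Sarcomonadea	phagotroph
Katablepharidophyceae	phagotroph
Syndiniales	parasite
Perkinsea	parasite
Chytridiomycetes	parasite
Peronosporomycetes	parasite
Gregarinomorphea	parasite
Conoidasida	parasite
Ichthyosporea	parasite
Microsporidia	parasite
Phytomyxea	parasite
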