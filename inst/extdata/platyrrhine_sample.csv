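species,n,body_mass_g,primary_component,hard_object,diet_category
Alouatta palliata,7,6250,leaves,FALSE,folivore
Alouatta seniculus,5,5950,leaves,FALSE,folivore
Aotus vociferans,9,703,fruit,FALSE,frugivore
Ateles geoffroyi,9,7535,fruit,FALSE,frugivore
Brachyteles arachnoides,9,8840,leaves,FALSE,folivore
Cacajao calvus,10,3165,hard_objects,TRUE,hard_object
Callicebus caligatus,2,880,fruit,FALSE,frugivore
Callicebus cupreus,8,1070,fruit,FALSE,frugivore
Cebus capucinus,9,3160,fruit,FALSE,frugivore
Chiropotes santanas,8,2740,hard_objects,TRUE,hard_object
Lagothrix lagotricha,9,7150,fruit,FALSE,frugivore
Pithecia irrorata,9,2160,hard_objects,TRUE,hard_object
Saimiri boliviensis,9,811,fruit,FALSE,frugivore
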