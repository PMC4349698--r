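table_name,tree_name
Callicebus discolor,Callicebus caligatus
Callicebus moloch,Callicebus cupreus
Chiropotes satanas,Chiropotes santanas
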