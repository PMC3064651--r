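((Clethrionomys_glareolus,(Arvicola_terrestris,(Chionomys_nivalis,(Microtus_arvalis,(Microtus_cabrerae,(Microtus_duodecimcostatus,Microtus_lusitanicus)))))),(Apodemus_sylvaticus,(Mus_pahari,(Mus_famulus,(Mus_cookii,((Mus_spretus,(Mus_spicilegus,Mus_macedonicus)),(Mus_musculus_domesticus,(Mus_musculus_musculus,(Mus_musculus_castaneus,Mus_musculus_bactrianus)))))))));
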