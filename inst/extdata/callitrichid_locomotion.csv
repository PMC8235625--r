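species_id,category
Callimico_goeldii,VCL
Callithrix_geoffroyi,VCL
Callithrix_jacchus,VCL
Callithrix_kuhlii,VCL
Callithrix_penicillata,VCL
Cebuella_pygmaea,VCL
Leontocebus_fuscus,VCL
Leontocebus_melanoleucus,VCL
Leontocebus_nigrifrons,VCL
Leontocebus_tripartitus,VCL
Leontocebus_weddelli,VCL
Mico_argentatus,VCL
Mico_humeralifer,VCL
Mico_melanurus,VCL
Saguinus_bicolor,VCL
Leontopithecus_chrysomelas,HL
Leontopithecus_rosalia,HL
Saguinus_geoffroyi,HL
Saguinus_imperator,HL
Saguinus_labiatus,HL
Saguinus_leucopus,HL
Saguinus_midas,HL
Saguinus_mystax,HL
Saguinus_niger,HL
Saguinus_oedipus,HL
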