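(((Leontocebus_tripartitus:4,((Leontocebus_weddelli:1.5,Leontocebus_melanoleucus:1.5):1.5,(Leontocebus_fuscus:2,Leontocebus_nigrifrons:2):1):1):7,((Saguinus_bicolor:5,(Saguinus_midas:2.5,Saguinus_niger:2.5):2.5):4,((Saguinus_imperator:4,(Saguinus_mystax:2.5,Saguinus_labiatus:2.5):1.5):3,(Saguinus_leucopus:4,(Saguinus_geoffroyi:2.5,Saguinus_oedipus:2.5):1.5):3):2):2):4,((Leontopithecus_rosalia:2.5,Leontopithecus_chrysomelas:2.5):10.5,(Callimico_goeldii:11,((Callithrix_geoffroyi:3,(Callithrix_kuhlii:2,(Callithrix_penicillata:1,Callithrix_jacchus:1):1):1):4,(Cebuella_pygmaea:4,(Mico_melanurus:2.5,(Mico_argentatus:1.5,Mico_humeralifer:1.5):1):1.5):3):4):2):2);
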