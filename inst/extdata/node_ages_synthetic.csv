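taxon,age_myr
Root,160
Asterales,93
Lamiales,97
Liliales,121
Fabales,108
Brassicales,103
Caryophyllales,111
Gentianales,102
Poales,113
Apiales,95
Malvales,99
Malpighiales,107
Ranunculales,128
Dipsacales,98
Asteraceae,49
Lamiaceae,53
Asparagaceae,55
Fabaceae,74
Brassicaceae,46
Caryophyllaceae,57
Rubiaceae,78
Poaceae,70
Campanulaceae,55
Cyperaceae,76
Apiaceae,50
Plantaginaceae,58
Cistaceae,42
Clusiaceae,72
Linaceae,71
Ranunculaceae,89
Scrophulariaceae,56
Dipsacaceae,51
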