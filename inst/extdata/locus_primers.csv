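name,sequence,orientation,locus
Pleth_12S_F,AAAAAAGTCAGGTCAAGG,forward,12S
Pleth_12S_R,GGTGACGGGCGGTGTGTG,reverse,12S
515F,GTGCCAGCMGCCGCGGTAA,forward,16S
806R,GGACTACHVGGGTWTCTAAT,reverse,16S
Bact-0341-b-S-17,CCTACGGGNGGCWGCAG,forward,16S
S-D-Bact-0785-a-A-21,GACTACHVGGGTATCTAATCC,reverse,16S
ITS1-F_KYO2,TAGAGGAAGTAAAAGTCGTAA,forward,ITS
ITS4,TCCTCCGCTTATTGATATGC,reverse,ITS
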