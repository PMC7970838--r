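>herring_mt16S_synthetic synthetic stand-in for the Clupea harengus mitochondrial 16S region (generated; not a GenBank record)
AACAATCCGCAATTCAAATTAGATGTTGCTCACACAATTTTCTGGGCGCTAGATTTATGGTTTATGAGGC
ACACTAATGGAAGTTCGGTCGGATAAGCCCCAAAATCATTCACAGCATCGCTTTAGATCTAAACATAACC
TTTGATAGGTCTGCATTTCTGTAGACTTGTGTGAATGTCCTGCTAATCCCAATGCATGGTTTATGGGCCA
CGCCCACCAATCACGAACTTAGTCTTAACCTGCCCACTGAAATTCAAAACGTGATACTGGCACAAACGTA
CACATATTTTACATTGATTATTCCCGGGTCCGCGGTTCATTAAGTGTAAAGATATACATGGGGCACATTG
GACCAACGGATGACGGTTAATCTATGTGGGATATATACTGTTTGTTACCTAGTCTGGATATTATACAATC
GGACCACAGGTAAAGTGTTATATAGTATGCATTTGTCAAAGGCTTAATC
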