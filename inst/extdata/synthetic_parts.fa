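>STAR50 category=STAR
AATGAAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATGCTT
>STAR10 category=STAR
AATGTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATAGCTT
>PlmJ category=insulator
GCTTTCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGAATG
>csy4hp category=insulator
GCTTCCTCAAGCCGGAGTCTAGGCAATG
>shcsy4hp category=insulator
GCTTTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAATG
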