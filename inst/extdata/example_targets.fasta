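>T1
UGCGGAAUACUCGGGAACACGCAGCUGAUGUUCCUACUGAGAUAUUCUCCGAUUACCUUGCAGGCCAACA
GCUGGUCUUGUGUUGGUCUGUGAAGAUAUCAUUCCGGCUGCAAUGGAGCGUCUGCGCGGGUACGUAGAUG
UUGCAGCCGGGGUGAUAUUU
>T2
ACCGGAAUACUCGGCAACAAGCGGCUGAUGUUGCUACUGAGGUAUUCUCCGAUUACCGUGCGGGCCAACA
GCUGGUCUUGUGUUGGUCCGUGUAGAUAUCAUGCCGGCUGCACUGGAGCGUUUGCGCGGGUACGUAGAUG
GUGCAGCCGGUGUGAUAUUU
>T3
AACGGAACACGCCCCAACAAGGCUCUGAUGUUGGGACUGUGGUAUUCACUGCUGCCCGUCCUGGCUAACU
GCUCGUGCUGAGUUAGUCGGGGUUGAUCUCAUGCCUUCUGCAGUGGAGGUUUUGGGUGGCUCAGUAGAAC
CUGCAGAAGGUGUGAGAUUG
>T4
AACGGAAUACGCUCCAACAAGGCUCGGAUGUUGGGACUGUGGUAUCCACUGCAGCCCGUGCUGGCCAACU
GCUCGUGCUGAGUUGGUCGGUGUUGAUCUAAGGCCUUCUGCAGUGGAGGGUUUGGGUGGCUCAGUAGAUC
CUGCAGAAGGUUUUAGAUUG
>T5
AACGGCAUACGCCCCUACAAGACUCGGAUGUAGGGACUCUGGUAUUCACUGCUGUCCGGGCUGGCCAACU
GCUCGUGCUGAGUUGGUCGGUCUUGAUCUCAUGCCUUGUGCAUUGGAGGUUUUGGAUGGCUCAGUAGAAC
AUGCAUAAGGUGUGAGAUUG
>T6
AAUGGCAUCCACGCGUCCCAGAGUAGAAAGCACGCACUGUAGGAAUAAAUACCGACAGCGCUCGACUAGU
ACUCGUCCCGCGCUGGUCUGUCCUUAACGCCUACUUUGAGGAUUCGCGGUGUCGCAUGUCCCCGAACACC
CUCCAUGAGGUGCGGGGUUG
>T7
AACGGAAUACGCCCCAACUAGCCUCGGAUGUUGGGACUCUGGUAUUCACUGCUGCCCGUG
>T8
AACGGAUUACGCCCCAACAAGCCUCGGAUGUUGGGACUGUGGUAUUCACUGCUGC
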