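>TPL1
AACGGAAUACGCGCCAACAAGCGUCUGAUGUUGGUACUGUGGUAUUCACUGCUGCCCGUGCUGGCCAACAGCUCGUGUUGUGUUGGUCGGUGUAGAUAUCAUGCCUUCUGCAAUGGAGCUUUUGCGCGGGUAAGUAGAAGUUGCAGAAGGUGUGAUAUUU
....(....)(..(((((...........)))))......(...).........)..(((((((((((((..........)))))))))))))((((((((((((((((((((.....(((((((....))....)))))))))))))))))))))))))
>synthetic_its2_canonical
GGCUGGACGGCGUUCGCGCCUCUGCGUGCGGAAACGCUCGCCAAAAACGGCGCUGGUGAAAACCAGCGCCCGGGCGCAAGCCCACCAGCC
(((.((..((((....))))...(((.(((....))).))).......(((((((((....))))))))).((((....)))).)).)))
>synthetic_its2_long
GGCUGGACGGCGUUCGCGCCUCUGCGUGCGGAAACGCUCGCCAAAAACGGCGCGGGCUUCGGCCCCACGCGAAAGCGUGGCGCCCGGGCGCAAGCCCGCGGUUCGCCGCACCAGCC
(((.((..((((....))))...(((.(((....))).))).......(((((((((....))))(((((....)))))))))).((((....))))((((....)))).)).)))
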