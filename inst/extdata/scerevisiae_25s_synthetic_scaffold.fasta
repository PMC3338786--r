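>scerevisiae_25s_synthetic_scaffold synthetic 3396 nt scaffold; authentic primer-site segments planted at published S. cerevisiae 25S coordinates, random filler elsewhere
TAAAAATCTTAGACTTGATATTGTCACCCGCTGAACTTAAGCATATCAATAAGCGGAGGAAAAGACCTAACTGGCTTTTCCTTGGGTAATATCGGGATTCTACTATCTTAGTTGGCGGCGAATATGTGGGCTCCACGCACACCCTCCGTAGTGATTGGTTTATAATTACATACGGAAATGATGTTCTTATATACGTGGAGGTATCGAAACCGACCAACGGTTCGGGTTTGTTCTCGGCTCTATTCCCACGGGTAACTTGCTGGCGCATGTGTGTATCATGGACTATAGTTATTTCCCGTACCCGTGAGGCGATATGCCTCATCATCACGGCCCGCACTACATGTGCGAATGAAAGCGGCCTATTATTCGGTATTTAGCGAGGCTGTCCAAATCTATATTACGGCTCTAGAGTTACAGCGCGTAACCCGCTCCTTCCTAGTGTCACCCCTCGGCGCAAAGCCCTAGCAGGCATAAACGGTGGGGGCGACTTTTGATGGCAAGGCTAACTGCAGATTGATGAAGGCCGCCTAGGTTGAGAGGTATAGCAAGCTTTCACGGCGCCACCATGGCTCTCATGTTTTTACTCAATAATCATTGTTGGAATTAGGGGCTACTGATATATATCGTTCCTGCATACCGTCTTGAAACACGGACCACGTAGCGTCTCGCTAGTACGAGTGTTTGGGTGGAATAGCAGTTCAGAGGGACAACAGTCCCGCCCATCGAAGGAAAGGGTAAGAGCGATATCCCTAACGCGGGCGTTCACTTGTCACCGCCACGTGACGTTGTAAGCTCAGAAAGCGCTGCTGCGGCCTACGACTATCAGACTCTCGATTTTGCTGAAACACGACCACTGTCGCCAAAGGCAGACAACTGTTTAAGTTCCTCCACTCGGCAGATAAATGGCCCGAAAGGCCAGACGGGCGAAAGCTTGTGTAAAATCCATTCAGAAGTTTCCCTCAGGATGACGCAATTTGCAATCCGTTGTGTCAGTGAACTCCTTACCAGACCTGGCTCATAGCAGTAGGGGTGTCGAATCCTCGCAGCACGTCGTAGAGTCTTTGAAGCTCCGATTTATTGTCGCGTCCAGTGTACGGCCGTCCACCAACACTAGGGACAATCAAACGGAGACTGGTATGATTTTTTTGGTTCAATCCTTGGTACCATAAAGTAATTTGTCGAACCATCGACCAACCATAAATTAAGGTGTTAGTTCATCTAGAATCGAGACTTTGCTAGTCTTGAAGCTGAGCACCTCGCGGACGAGGCGGCGAGGGCAGGGAGGACGTAAGCCTCTGCGGTAACTGTTTTCTGTGAAGCAATAAAGATTGCACCTACTACTCCGGGCGCTATTGGAGTTTACATACAATGAGTGGCTTCCTTCGAACAGCAAACACCGAGCGTTCACCTAGATTCTGATTTTAGACGGCCAAGATCTTGGTGGTAGTAGGGGATGCCTTATAACCGGCTAACTAATCGGGATAAAGAACCAATGCGAGGTAAAACTATCCCTATGAAGCCAGGCCGGGATCAGCTCCTAATGTTCCACGTCAACAGGGCCAGACGAAGCCTCCGGGAAGGATCCTGCGACGACGAGCGAAATCGGTGCGACTCTGCTCTGCGTGGGTCTGGAATGAACGTAGAAGAGCCGCTAACCAGACGAATGCCCAGGTCGAAATCGGCGCCACGCGCTTCTCAACACGGCCCTGTCCTTTTATAGTCACATATGCACCGCTCACGGGTAGATGCAGACACCGCCAATGAACAAGGTTTCGTCGATGGGTAGGGGCTCCGTCTGTACTGGGACCAGCTCTTGTTGCTAATGCTTAAGCATTGCGGACAGTGAAGAATTATGCGCCAATATTTGCCGCCAGTAAACTATGGCTAAGTTTATGATGTTCCTAGTTAGTCGAACGCAGAAGTCCTATATCAAACCGGCGAGAGAATCCGTCGCTTGCATAGCACGTCCTCACTCAATGAGCATTCATGGTCTATGGACGCGAATATATGCCGTACCCCAACGACGATACTGATGTCAGATGGACCAAATTGACAGATTGCTGTAAAGGCGGAAAGAAGCCCCAGAATCCGAGTCTTGCGAGCGGATGATGAGACTCACTGGTAATGGCTCTTTGCGAATGCGTCAAAGATATCCCGGGTGATGGGTTGTTGACAGGTTGCTCTTGTAACCTGGTGGAGACTTATCTAGACGAGCAGTGAATAAGGGGGCTTGTGTCTTTTGCGCGTTAGCCCTGGGCTACCCCCTCCATACTAAGCGGCATTAATTATAACCAGGTTTCCAGACATGTTCGAGATTCGTCGAAATGCAGTCCCGCGATGTCGCTCGGTCGGGGCAAATATCTGGTCACATGAGTGGCTGTGAGATACCAAGGCTCCCCAATGGCCTGTCGTTCGACGATGTTGCTACATTGCGCGATAATGATTGCCTCCTAGTCTTGCGTTGACCGAGCGGAAATCCTTTAGTGGCGAAAATCTGGCGCTAGCGGAGGATCTTGTCACTTCCTAGCGCATCGCCCCTGTGATGCTTGCGGCGCTTCGTCTATGTCCATCGACGATGTGGCGATGGAACCCATTAGATGTCGGACTGCAGCACAACTTATCTTTGGATGGGATCGATGCATGTCTAGACATGGTATATATGACACGCTCTCAAACGAAAGCGCAAGCTTGGGAGGCGCAACCTCAAAAGAGGCATTTGCCGGTTCAGGGTCTCGGCCTCGATCCCTGACCTCCGTCACCAATATCCTACCCAACATCATTACACACCTGTCACTCGTACGAGCCCTCCCCCAATGTTATTAAACGATCAGTCGATATTCGAAAATCTTTGTAGGTCGTAGATGTACAGTGCTAAGAGCCTTTCCCCGCGTCCGCCGAAGTGTTAGGAGTACCTCGGCTCCTAGGTCGGTAGCAGGCTGTCCTATCAGTATGGAGTGACCCTCGATTCCTTGATTGGTGTACTCTCCTTACCAGAGTGCGGGTGCCTCGCGCTCCGAGAGGTCCCGTTGTGGCCGCGGTACCGACCAGGGCGGTCTTGATTGTCCGCATAGGAACATCCATGTCAAGTAAAGAGGGAGCATCAGCCAAAACACACAATTATATCAGCTGTGTTAGTTGATAGATTGTCGAATCGCCCGTCGCCGTCTAAGCCCCCTCTTAGGGGATCTCTACGTCGGGTCACGGTGCCTAAACTCCTTTTCAACTTGACAGCTTCCTAATTTTTGTTACTCGCGAGCTTTAAGCTGGGCTGGAGGAATCTCTATAGACTGAAAGCTGTCCGTGCCAAGCACCTATTGGATCAGATAGAAACAGTCTCGACTCTTGTCCATTGAATATTACCACAGACAGCATCCTAATAGGACATACTCGTCGACA
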