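>Du215|armeniaca|1
CTCAGTTAACTATCCGTAATTCTCACCGGTGCCGAATTGTGATAGATAGATAGATAGATAGATAGATAGATAGATAAAGCTTGCAATGCGCATTGGAACAATACTCACTGAAGGGG
>Du215|armeniaca|2
CTCAGTTAACTATCCGTAATTCTCACCGGTGCCGAATTGTGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAAAGCTTGCAATGCGCATTGGAACAATACTCACTGAAGGGG
>Du215|armeniaca|3
CTCAGTAAACTATCCCTAATTCTCACCGGTGCCGAATTGTGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAAAGCTTGTAATGCGCATTGGAACAATACTCACTGAAGGGG
>Du281|armeniaca|1
CGCCGGTACCGTTCTAACGTGCATTGGTAGTCCCGGCCGAGATAGATAGATAGATAGATAGATAGATATATAGTACATTGCTAGATGGCCCCACCCCAACCAGCTAAT
>Du281|armeniaca|2
CGCCGGTACCGTTCTAACGTGCATTGGTAGTCCCGGCCGAGATAGATAGATAGATAGATAGATAGATAGATATATAGTACATTGCTAGATGGCCCCACCCCAACCAGCTAAT
>Du281|armeniaca|3
CGCCGGTACCGTCCTAACGTGCATTGGTAGTCCCGGCCGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATATAGTACATTGCTAGATGGCCCCACCCCAACCAGCTAAT
>Du281|armeniaca|4
CGCCGGTACCGTCCTAACGTGCATTGGTAGTCCCGGCCGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATATAGTACATTGCTAGATGGCCCCACCCCAACCAGCTAAT
>Du323|armeniaca|1
ATGCTGCGACTATCGAGTGACTTGAAACCAGCAGTTAGGCGATAGATAGATAGATAGATAGATAGATAGATAGATACCATTTACACACACACACAAAAAGAGCCCACATGTTCAATACTTGGCTTCTGTCGTGA
>Du323|armeniaca|2
ATGCTGCGACTATCGAGTGACTTGAAACCAGCAGTTAGGCGATAGATAGATAGATAGATAGATAGATAGATAGATAGATACCATTTACACACACACACAAAAAGAGCCCACATGTTCAATACTTGGCTTCTGTCGTGA
>Du323|armeniaca|3
ATGCTGCGCCTATCGAGTGACTTGAAACCAGCAGTTAGGCGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATACCATTTACACACACACAAAAAGAGTCCACATGTTCAATACTTGGCTTCTGTCGTGA
>Du47G|armeniaca|1
ATTTCTAAGGATTACGGGATTGCAATGCTATGGGAGCTGAGATAGATAGATAGATAGATAGATAGATATCTATTTAGTAAAAATATCACAGTTTGGAATCGGTGATAT
>Du47G|armeniaca|2
ATTTCTAAGGATTACGGGATTGCAATGCTATGGGAGCTGAGATAGATAGATAGATAGATAGATAGATAGATATCTATTTAGTAAAAATATCACAGTTTGGAATCGGTGATAT
>Du47G|armeniaca|3
ATTTCTAAGGATTTCGGGATTCCAATGCTATGGGAGCTGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATCTATTAAGTAAAAATATCACAGTTTGGAATCGGTGATAT
>Du47G|armeniaca|4
ATTTCTAAGGATTTCGGGATTCCAATGCTATGGGAGCTGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATCTATTAAGTAAAAATATCACAGTTTGGAATCGGTGATAT
>Du47G|armeniaca|5
ATTTCTAAGGATTTCGGGATTCCAATGCTATGGGAGCTGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATCTATTAAGTAAAAATATCACAGTTTGGAATCGGTGATAT
>Du47G|armeniaca|6
ATTTCTAAGGATTTCGGGATTCCAATGCTATGGGAGCTGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATCTATTAAGTAAAAATATCACAGTTTGGAATCGGTGATAT
>Du47G|armeniaca|7
ATTTCAAAGGATTACGGGATTGCAATGCTATGGGAGCTGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATCTATTAAGTAAAAATATCACAGTTTGGAATCGGTGATAT
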