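>TRAV1|01|V|TRA
AACGCCGACCCTCAATGGGAGTGAGCCATCTCAATTAGCAAGCTTGACTGTGCTGTG
>TRAV2|01|V|TRA
CGTCGAACTAGCTGGTCGGGCTCGAATGTTTCCATTTGAACCGTTGCGCTGTATTCTG
>TRAV3-1|01|V|TRA
TTTGTGACTTGTGCGTACGTGACGAATAGCTCGTATACGCAGCCTTCGTGTGCTACT
>TRAV6|01|V|TRA
ATCAGCGACTAGGAACGGTATCAGGGCCCATAGCCGATGCCCCAGTTGAATGTGTGCTG
>TRAV9|01|V|TRA
TAAATTAACGCGCTGTGATAAGGTATAGAGTGTCGTGTAGCAACAGGATGTGCTATG
>TRAV11|01|V|TRA
GGCGTTTGAATACTGATCCCTAGTGCCTACGGCGCTGGAGTCTATCATTGTGTGGTG
>TRAV12D-1|01|V|TRA
GTCAAATAGCACAAGAAGTTGCAACTATTCCATTGAAAATACGTCCGATGTGCTCTG
>TRAV13|01|V|TRA
TCGAATGAACTACACCTATCGTTTGGCGATCCGCTATCGGTCAAACCATTGTATGGAA
>TRAJ12|01|J|TRA
TCCGCACTGGTGGTTATAAATTCGGATATAGTGAATTATTGGGGCAC
>TRAJ18|01|J|TRA
TTCGTGATCGTGGTAGTGCTCTGGGTCGTCTGCATTTTGGATTTGCCAATCTTCTTTCCAAC
>TRAJ22|01|J|TRA
CCGCCTAGTAGTGGTAGTTGGCAACTGATTTTTGGAACGACTAACGGCGCCTAGGCA
>TRAJ26|01|J|TRA
CACCAATTATGCTCAAGGTCTGTTCGGATGCAGAGCCTTTCCAACAACG
>TRAJ33|01|J|TRA
CCTAGATAGTAATTATCAACTGATTTGGGGAGACGGGCGGTATTCGTAGACC
>TRAJ40|01|J|TRA
GAAGGACTGGTAATTATAAATATTTTGGATTTCACGTTGGATTTGCGATA
>TRBV1|01|V|TRB
TTCCGCGAATGGGAGAAAGATGGAGATTTTGCGTCCACGGCGGGAGACTGTGCTAGT
>TRBV2|01|V|TRB
GACCGGCCAGGGGAGAGCACTTGGCAGCCCGCTGATCCCGTGCAGGGGTTGTGCTTGG
>TRBV12-1|01|V|TRB
TCTAAGTATGCTATTGCTTGTTCTCGCCCGCGGTGCTAGGGGCGCCATTGTGCTAGT
>TRBV13-1|01|V|TRB
TTACTGTCCGATCCAATTAGCGCTCCCGATGGGCAGATAAAGGCTAAAAATGTGCTCTG
>TRBV16|01|V|TRB
GAACTTGGTAGCGCCAAGACACGTTCGGAGTATCAATAAGGGGACAACTGTGCTATG
>TRBV19|01|V|TRB
ATCAACCAGGGCGACCTTACCGTCGCCGTGTATGTGTTCGCAGGCTACTGTGCTAGT
>TRBV26|01|V|TRB
CATAAGAAAGCCTAAATCTTCCCCCGACAGCCTAGCCAATTGCCATGAGTGTGCTGGT
>TRBV31|01|V|TRB
GTTTAAATTGATTCCTCCGATTGTAAGGCACAGGGGGGCGGTTGCGACTGTGCTTGG
>TRBJ1-1|01|J|TRB
TGTCTAATACTGAAGTGTTCGGATAGACCGGAATAACTAAGTTC
>TRBJ1-4|01|J|TRB
GTACAGTAATGAACGTCTGTTTGGACCTGCTCTAGGGAAATGGCCC
>TRBJ2-1|01|J|TRB
ATTAAGAATTATGCTGAACAATTCGGACACGGATGGGGGCGCGATCGA
>TRBJ2-3|01|J|TRB
CATTTAGTGCTGAAACTCTGTTTGGACACAGTTCTCCGATGTGTTGT
>TRBJ2-5|01|J|TRB
GCGCCAAGATACTCAATTCGGAGGCTAGACGACACAACATTCA
>TRBJ2-7|01|J|TRB
GGCGCAGTTATGAACAATTCGGACTGGTGAGACAAATACATACG
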