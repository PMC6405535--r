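>punctigera_coi5p_698 synthetic coi5p_698 amplicon (punctigera)
TATATTTGAGAAAATTTACATTCGTATTCATCTTCAATTACTTTTCTTAAATCAAAATTCTTTTTTTTGA
TAAATTAATTATTTCTTTTGGACATAACGAGAATAACAATATTTAGGCAAAAGACGCAGAAATATAGAGA
CAACTATATTGAATAAAATTCATAATTTAAGTTTCGTTTTTTTATAATATATTTTATCCTACATTTTAAT
GTATCAAATAATATATTAGACTTTTTAATATTTAAAGTCTAATCAATCATTATGGAAATTTTAAAATCTT
TGTATAAATACTATACCTATAATTCTGTAAAATATATACTTTCTGAATAATTGGTAATCTACTATTCTGA
GAATACGCTTTGTTTTAAGTGATCTTATAATAAATATATTGTAAAACATATTATTTTCTCGTAAAGTATA
GAGTGAATCTATAATTTAAAATCAGATGCTAATAATTCTTAATAAATTTTAGCTTGAGTCACTAAAAATG
GTTCAATATCATTAAATCAGATTATTTCCTTTTATAAGATATAGATTGTATCAATTCTAATTCAGGTAAT
GATTACGAATGTTTATTTTAGATTAATATATTTTCTAATATCGATTAAATAAGTATACTTTTAAAAAAAA
ATGTTTCGCATAAATGTTGTATATATGTATATTTTAACTAAAAAGTTTAGCTAATTTTTTTATTAATA
>armigera_coi5p_698 synthetic coi5p_698 amplicon (armigera)
TCATCAAAATTGGAAATTTTATTATATATTATAAAAAACAATCAAATAAAATTGATTACCAATATGTAAT
GATACGTCAATGTTTGAGTACATATAGCTTATAATATATTTGGTCAAATATTCAATAATAATTCTACAAT
TATGTAGTAATTAATGTTTTATCATTTTTAAGATTTGTAAAAACTTTAAAAAATATTTATAGATTATTAT
TTTGACGGTGCGTTATCCTCTTACTAATTCTATGAAACACGTACTATATTTTAATTAGTATATAGGTATA
ATATTTAAATATATATTAACAATACTGTTAAATGAAAAATTTTTATTGAGATATACAATAATTGTTTCAG
AATATAAGAATGGGTTACACCGGAACTAGATACATTTTCTTCTATATTAAAAAATAAATTCTACAGTAAT
TAAGAAATTCTGATAATCGAAATAACATTTTTTATTAGACTTAATATCTGTAATATTTTAAATAATTTAT
GCTCCGTTATCGTCACAACAATTGTTCTGTAAGTCCATATTATTGCATTTAAATGAATATTATGAATATA
ACATAAAAACTTAATTAAATTTCTATTTATATTTTTTCTTCATATTAACATTCTTTACAAATATTAAAAA
TGCCAGTACTTTAACTGGGGTAGATCTCCTTAAAATTTTAAAAATGAAAATAATGTTTTTCATGTAAG
>assulta_coi5p_698 synthetic coi5p_698 amplicon (assulta)
TAAAATGATCCCTTCAACAGAGTATAGTAAAACTTATAATGATTCATTGATAGAAAAAAAATTTACAATG
TGATAATTTCATTAGTTCATATAGGTCAGTAAATAGAAAATATGTCTAAATAAGCCATTATAGTTAATAT
ATTGACATTACCTAGTATAGTATTTTTTTTACATATAAAGCATTATGTAGATGACGAGTTACGGTTTTTT
TAAAAGAATATTTAAATTATATGAACAAATACTCATCATTTAAAAAAATGTAGATTGAATTTAAGAAACT
TATATATTAATTAATTAATATTGTTCTTCTCTAGAATACGAGTAATATCTAAGGTAAAATTCTTAACATT
ACCGTAATATAACGATTATATACGTAAACGAATTATTAATAAACTTGGAGGAGTTAATTTTAAAATCGTT
CGATTATGTAAACATAATATCTTCTATATTAAATTTGATCGCCATCAATAAGTTCTATAAGTTATTATAA
CTTATCCGTTTTGTCTAAAATTACAAGCATAATTGAATCTTACTAGAATCGATCTAGTATATTTATTAGA
AGATTACAAGTTACAGTGAAGAACTTTTCTATTAATTAACAAACTGATATTAGAATTATTGATTAAGAAG
TAAATTTGTGAAATAATGAATAAAAATTGTAGAAAATTAAAATATCATCTTTATATAGGTAAATTCTT
>zea_coi5p_698 synthetic coi5p_698 amplicon (zea)
ATCTTGTTAATTAGATAATAAAAAAGTAAAAAGAAAGATATTTAAAAAAACAGATATTTAAAATTAATAT
TTCAATAATTGATGATCTTAACTTTAAACTTTTGTTTTTAACGTTTTATAACAACTTCTGTTATTGACAT
TCTCATAATTTGATGAACCTGGTTAACTATGTATATATAATACTATAATGCCGATATTTCTTATGGAAAT
GATAACTTTTTGCATTAAAATAGTAAAAAACACTACATTATATATAGTCAATTTTAAACTTTGTGTTATA
TAGAATATAAATGGATTAAACGATGTATAATAAATCATATTTTAAAAACTTGATTTCTTGGTAAATTATT
ATCTTAATAGAACAAAATACTACTACAAAAGATTCATTTGTATATATTAATCTATGCATAACTTTATATA
AAGAATTATAAAAAATTAGATACTATTATCTCTAATTTGTTTTTTTTTAAAAATTTATATGTAAATTCAT
CATTACTGTTATATATATTTCGGAGCTAATTTACCACTTTCTATCTTATGAATAAGTTTTTATCTTATAA
ATCAATTAATTATACCAGGTCTCTCTTTATTTTAAATATTAAAATTCCATCTAGTATATTGCTTATATTT
AACTGCCCTTTTTGGAATGTTTAATTTATGTTTTTATTATAAATTTATATTTATTTTTTAAGATAAGA
>gelotopoeon_coi5p_698 synthetic coi5p_698 amplicon (gelotopoeon)
ATAAATAAAAAAAATTTCATATTTATTCTGTATTGGTAAAAGAACTTACCTAAATTTGGAAAGTTAATCC
AATAATAATCAAAAGGTTAGTCTTATATTAATACATATAAATATCGTTTAGTTTTTAATATTCTCAATCC
GTTATATCGAAAAGAGTGGAATGAAAAATTTAAACTTAATAATATCACTAAATGATTCTATAAATATATT
AATTTGAAAGTTTTTTTCTTATCTTATTTTAATTTTATCATCTTTAATTTTTTAATTATTACGAATTAAA
AAATTTATATACTTATAATACTATTTTTAAAATAAGGACGTATAGTTTTTGAATATATTATTTTTTATAA
AAGTTAACAATATTATTTAACAAACATAATTTGAATTATTATCATAATGTGTATACTTGCTTATTCATCG
CAGAATTAATAACATTATAGAAGTAAACTATTGTCCGATACAATGGTAAAAGGTAACAAAATAACAAATA
TTCATATCATATTATGTATTATTTAAGATAATTAATGTTAAAGTCATGAAGATTCCAAATAATAGAAAAA
GAACATATTATCTTTGATTAATATGTTAACTCTTTTTTAAGTTTTTTCCAATGGTATATAAACTCACTCT
ACTTATGATTCTAAAGGATAAGTTTAATATATTAATCACAGAGTGTTCTCACCTTATTTATAACTATA
>punctigera_coi3p_511 synthetic coi3p_511 amplicon (punctigera)
TTATCCTTTTGCTGGTTTAGACTATAATATGTAATACGTCGTTGTGTTTTTTTGACTAAAGTCTTTATAT
GTCTTTTAACTTATAATTTAATAAAGAAACACACACCATCATATTATTAACTATTCTATATGTAGTCTAA
TCTCTACATAATTAATTATTTAAATTAAATACTAATTAACAAACTAAAATTTAGTACTATTCGTTAAATA
AATAGTGATTAAGAAGTTAAAAGATATCTCTAAGATAACTATAATGTTTTGTTGAATACTTTGTCTTTTC
GAATGGTTTATTCTTATGAATCGCAACTCATAATTGCATATTGGGGTACTAAACGTTGATGATTTGCGAA
AATTTATATCCCAGTAATTAACAGGTATTTTGTTTCAATAAAATTGCATAAGCTTAGCAATATTGTATAA
ATAGAAAAAATTGAACATAAAGTTATTTTCAGGAGGAGTTAGGACGGATGGTATAATTAATAATCTAAAT
GAACATTCTTTACCAAAGCAA
>armigera_coi3p_511 synthetic coi3p_511 amplicon (armigera)
CACACTACAAGCTACTAAACTATGACTTTTGCTCTTTTTAAAAGTTACCATAGTAATTGTCGTATTAATA
ATAAAATGAATTAATTTAATTCGTTTAAATAGTACTTACAATACAATAAATTTAAGAAATTAACTAATGA
GTTATATACAAACTTGTGATTAAAGTAACAGAATTAAAGTTCAATAAAATTTTAAGAACAGTTTCTTGGC
TATTTAAGAATTCATTTTTGTTATTCTAATTAATGATTTAGTTTACTCTGCTTTAACTTTTATGGAGAAG
TAGGTAGTTTATCAAGTAAAAACTGTGTTTTGTCAAGTTTTATATTTTCAAACTTTAATTTAAATTGATT
AATGTGTAGCCTATATATCATAGATTTATTAAATATTAACTCATTTCATCGAACTTTAAGAAGTTCATGT
ATTATAATTATAAAAATGTATATATATTTATGGATAAACTTATATTTGTTTTCCGTGTTAAAAAAATGAA
ATTATAATTTTAAAACCTTTT
>assulta_coi3p_511 synthetic coi3p_511 amplicon (assulta)
TCATGATCAAATTTGGAAACTTTAACATACTGAATTATCTGTCGACATAAACATTATCTTAGACGTACAA
ATCCTCCTTACATTCTAAATTAACTCTACATAAATTCAATTATATATTGATAAATTTTTTGTTATTCATC
AATCACAATGTGTCTTTATTAGTAATTATATTATTCTTAAAATTTATCAATCCATGAATTTTACAATTTC
TGCTTCAATAACAATAAAATTAGACATTAATCATTTTTATGGTATTAAACTTCTGGTACGTGATGAAACC
AATTCAAGTTAAGGGAATTCAATAAATCTAGGATATATAGATAAATAGAATTTTTCCTATCCGATCATAT
AAGTAAATCTTAGTCGTAGGAACATGACATCGTTATTTTAATTACATATCTTATAATATGACGAAAAGTA
AAAACAACATCTGAATGTCACATAGCCTATTAGTAGCGTATAATCTATGAAAATCAAAATACAATTATTA
ATAATCATCTTTCTTATCTAA
>zea_coi3p_511 synthetic coi3p_511 amplicon (zea)
TTAAAAATTATAGAAAAAGTTTGAATTTTGTAAATATCATATTTAGTAGAAACCATTTAAATTATAACAA
ATTTTAACATTATCTTTTTAAATCCTAAGATATAATAAGAATTTTTTAAATATGTTCAAGGTAGATATCT
TTAAATCTTTATACACAAAATGTATATTTATTATAAATATAAATTGAATAGGTAATAAAAAAAACCTAGA
TTTATAAATATTACTAATAATAAATTATGATCGGCAAGTCGTTACAGTAATATATTTAATAATAAATAAA
ATAAAAGATTAATTAATCAAACAGATATGTTTAAAAATTTATTTTGGTAATTATATAGATCTGTTATAAT
TTCTTTATTTTTTATTTAAGATTAGCAAATGTAGAGATATTCATTTAGATAAAAAAACTTTATATAAATT
TTGTTAATTATTTAAATAGAAAATTTTTAGTTAAATTGTAATCCACTTTTATTATGAAGAACCACATAAT
CTCTGATAGATTATTATTAGA
>gelotopoeon_coi3p_511 synthetic coi3p_511 amplicon (gelotopoeon)
GTTTAATAAGTCTTAAAAAATTTATAATAGTACGTTAAATCAATTATTGCTGAAATTCTACGTTAAGCAA
TATTTAAGTAATTAAAAAGTCATAAGTTATACAATATTAAATTGTATAATACATTAAGTAATAACTCTCC
TATATAGTACTATTAATTTTAAATAGATTGTTAACTTATCATATGATGTAGAATTTAATACTAACTCTTA
CGACTTACATCAATTTGAAATGAGCTTAAATTAAAATAACTACGCACCTGTAAATTATTTACAGATACCA
ATATAGGTAAAGTGTTTAACCTAGGTAATTTTCAATTCAACTAAAATTAACGTAATAGTTAGGTTTAAAT
TAGTTAAAAAATTACTTTATATATGGTTTCTAGTTCTAGATTTTATTTATAGGGAAGCTAATACTTAATA
TGGTGTCTTAATGTTTGGTTTTAGTCTCTTTAATAGGTACGAAAAAGTATATTCTTTATCTAAATAAAAT
TATCATCCGAATGTTTCAGTT
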