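AACATCGA
GGCATAAC
GTTGCGTG
AGACAGTG
CTACACCT
TTACTTAG
AACTAGAC
GCTGTGGG
TCGCTCGC
CCAGTATT
ACGCGTAA
TCATGCTA
AACTACCT
ATGCATCC
TCAGCTTC
TCCCTTAT
GGGTCATA
CTAGCAAA
GTCGTTCC
CCGGCACT
GCAGGTCA
GCTTGATA
TGTTTGAC
GCCCGACC
GAGACGTA
AAGCGTTC
CCCGCTGA
TTATTCCG
CTCTCGTG
AAAGTGAT
ACTATCAA
TCCAGCCA
ACAAGATG
GAGTATCT
TCCGACCG
GAAGCAAT
TCTTAATC
ACTTTGAG
GCATTCAA
TTAGGATG
GTCAGAGA
GTGACTGT
TGGGTCCG
CTTCTAGC
TGAGCGGT
CGATTAGA
CAGCATAC
AATGCGCC
CCGCGGTC
CAGCACCA
GTTTGACC
CGGATTCG
CCAACTGT
GCTGTCCT
AGCAGAGT
TGATGCAT
GTAGCCTT
TACCTCTG
GGGACGCG
CGGGATCA
TCACCCTT
TTGTTGTC
GTGCCGTC
CTGAATTA
AGCTCTTG
TATCCCAG
ATGATATA
GCCCGGTG
ATATCAGG
TTTCTGTT
TGCGGGCC
TCTGTAAA
GTCCGTCG
AAGTTGTG
TCATTGGT
GCTGAAGA
GTCAAATT
CCGCTCAG
GAGGTACA
CATAGACT
GCGATACG
GAGCCCGA
ATTTAGCA
TTAAAGCC
CGAATGAG
CTGTTAAC
GACCTCGC
GATTCCAT
TTTCCAGA
TGGAAGAT
GAGGAAAC
AATAGCCA
ACCTGTTC
CTTGACCC
TCACGGAT
AAGGCTTA
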