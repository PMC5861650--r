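loci:
- name: CEPsyn
  sequence: ATCTACGCAGCACTTTAAAACCTCGCGAGCTATGGGAGCAAGACGACTAGGGAGCCACGAACTGCCTTGTCAAGCACTCAATGTACTGACGCCCTCTGACGCGTACTGGGTCTCTATCGGCCTTGTATAGGGAGGAACTGTCCCTAGAGATACATGATGGTCGAGTGGGGGTCAGGCGTTAAATGAGCAATTCTCACGTGTACTACTTGCGCCCGTTTGTTCCTTGCATCCGCAGGCTCTGCGGGGAGCTCATACTTTAATCCTAAGTGGGTCATGTCAGAGACCTTTTAGACTGGAGCGAGCTAGTTCCTGTACCTCGAACGAGAACTTATCGGATCGGAGAGGTGCCGCGCGACCGTTTGCTCAATGTCCCCTCTTCAACGTATATTTGCGGTCGTCGGTGGACATACTCGACCTCATCATAGATGTCTCTACTACTAGAGTTTCGGCAATACTATAGGTAAATGACTACGGGGAGTCCTAACTTGCCCTGATTTGACTATTCAATCAAGAAGCAAATCTATAGCGGATCGCCGACGTCCAAGCGGTCTATTAAAGCAACCCTACAAACGCCAATTCGGTTCCGTAAGATCAAAACGAAGGTGGAAGGGGAAATGGACTACGCGCTTTGAAGGGGTGTGCCTATGCACCGGTGCGCCCGACGCGGGTCTTTACCGCTCTGGTGACTGCAACTCCTAATATAGGGTGAAACAATTGGAAAACGAGTGTCAAAGTTCTCGCGAGTGCTAGCCACACGATAGGGGCGTGCACGGAAAAACGTCTAACACTACCATATTCGCGAAAACGATTGCTTACTCCCTGCTCCGCCCAATGCAGGTGATATTTTCGAGAGTACACGAGATCGCCTGTGCACAGACCCTTGTGTAATACCCAACAAGTACAGCGTGCAGAACCGTAACCGGATTGTTGTCTGAAGGGCTACGCCACGACAGGAACGCCTTGACGGCAGGCAGGTAGGTGCACTTCCCGCACGCTGTAAAAACTTACATATAACAGGGGGTATATGCATTCTCGGGCAACTTCGCGGGCCTGTGCAGTCTGTTGCAAGATACAACTCTTATTCGCTTTAAACATGATCCTCGATCGCGAACTTCGATCAGCCGGACTTGCCCTCGTAACATGCCGGCATCTTGATAAACTATGACCGAGCACTGGCCGCTAGAACTGTGCTAGAAACTGACCCGTGTTAGGCGAGCCATGTTCAGATCCTCCATCCGAACGTCGGGGCGGCAATGCGGCAAACGTCTCATCTCCGAAAGTTATGATGGTTTACAGCTCCCGACGGACGGTAGAGGCGCCGGTAGAAAAATGGTACGGATTTAGGAACTCGTAGAAGCCTACAACGAGCGGTCCCCGTTGGGCTTTAAACATCTCGACGGCCACGACCTGCGCGCTTGTCCCAGGAATTCCCCATAGGAGGCTAAACCAAGGAATGGAGGATGTTAACTCGCGTGACTGGTCCACTCACGACATGGTGGAGAAGCGTTGTTAATGCGCCCCCAAGGTCTACTGAAAGCCACTAACAATGGTATCCCAAACCGGTCATCGGCGTAGACGCATCTTCGTGTTTCCCAGCTCACTTGGAGCCTTGCGCGAACTTCAAGTAGAGCATTACACTGAATCTGATTTATTAGGTAGGCAGTTGATCCCCAAGTTACGGATTCCCTAGACGTGGCGAAGGTTTCGCGTGCCGCTTACCGGGGTTGCTTTCGGCTGTGAGTGTAGAACCGTGGATCACCGCTCCTGGAAGCCGCAAACGGAGGAATATGCTTCCCGTTTGTGTAGAAGCCGATTTCATTTGCTCCCCAAGTGGTTACCTTAGGTGCTTGGTCAAAAATCGACTATAGCAGATGAGTGTATCAACATTGACAGGCGTGCAATCTGTCGTCGACTTTAGCAGTTCACCCGTAGCCTCAGCCCGCTACAGTCACACCCCGGGGAATAGCATGCTATAGTAAGGGAAATTTAGTACTTTCTTGCTACAATAGACCAAGGGGGCCCCGGTTGTATTGTGTCATCGTGTCAGACCCTTGGAGTATTATCATCTTAAACCTTCACTATTACAAGGTAGATCGGGCCACCCATGGTAGTCAAGAGAGTATATCGCCCAATTCCATTCGCCGACCTTAGCTTTGGAATCTCGGCAGTCGCAAATCGTTTTATTGACGACGGCGACGAGCGCTATCACGAGTATACAGCTTGGATTAGAGAAAAGCTAGTAAGTGTGGATGTCACTTCGTAGCCCTAAGAACTACAATTGACGGCGTATCGACCGCATAGACCGCAACCCCTTTCGGAGACTCCGCCTCATGGATAAACGGCACCCTTTTAACGCTCTACGGGTGTAGTCACGTTTCGGGACGAAGCCTCCAGTGTACTGAAAATATGGCAAGTCGTTGTACGTGGGTACCTATTCGTCCTGTGTATGTCTCCTGAGTCCCGCCCTATGATGAGGCAAAATCTAGCTTTCGTCGAACCCAAAAAAGGTCGCGCACAGTCAGCCTCATTACTACAGGACTTTGCGGTCAATAACTGCTACTCACACTTTAGGCCCTGACGTCATAATATGCAGTTGCCGCGATTTTACTGGGTTACGCAGATCAAGACAGGTCAAAGCATCGGCGTTATACTGGTCTCGATCCGGCGAACCTTTACTTTTTTGGTAGAAACCCTGCCACGGGTAGCGGGCATACCAAATGTAGAGCGTGTACGTAGAGTGAGTAACTGATGTATTTCTAGAATAGTGGAACTTTAGCCCACATGGAGTGAGTCACCATCAGAGTTGCGCACGGACGAGCTTGGCCTCTAGGAAACATCACGTTCGTCAAGCTCGATCATTTAACATCGGTTTTGATGGGACATCGGTATTATGACTCAATGCCTATGGAGTATTGGGACCCGGTTTCTCTAGCAACGACGGTTGCACATAACATAGTCATCACCTTTTATCTTCATCTTGTGTCCGCCGTTAATGATGAA
  chrom_label: chr12-like
  centromere_side: LEFT
cuts:
- locus: CEPsyn
  position: 1000
  guide: g64
- locus: CEPsyn
  position: 2176
  guide: g323
primers:
- name: p323
  guide: g323
  side: RIGHT
  distance_to_cut: 100
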