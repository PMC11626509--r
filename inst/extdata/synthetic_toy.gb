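LOCUS       SYN_TOY                339 bp    mRNA    linear   SYN 01-JAN-2026
DEFINITION  synthetic toy transcript, mRNA.
ACCESSION   SYN_TOY
VERSION     SYN_TOY.1
FEATURES             Location/Qualifiers
     source          1..339
                     /organism="synthetic construct"
     gene            1..339
                     /gene="TOY"
     CDS             10..309
                     /gene="TOY"
                     /codon_start=1
ORIGIN
        1 aaaactccaa tggtccaatc aacacagacg gttccacgtg ctgtcttaaa gcagcgcaca
       61 acgatcaggt ctccaactcg aaaattaggt atgagtcaaa ttagcctcca tggttcgaca
      121 ttgcatccta ggcgatcttt gactgaagct acccaacacg tggcgcgtgc ttcctccttc
      181 gcattagatc cgttcgacaa tggttacaaa tctatggtga acacaaggag ttatcggtgc
      241 ccatatagca cccggctaac gcgagaagtt tctcgagatt tccctcaagt gccttctgtt
      301 aaagactaat atatgccgaa cgttctaata aacgactta
//
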