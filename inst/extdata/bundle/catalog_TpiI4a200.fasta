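>AfrCa1a synthetic stand-in for GenBank PV125350
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTCAACAC
CACCATATAGAACAGAGTTTACCTCAACTGGTATCAGGGGAACAAGATTCCTTAGAAAATGTTAGTACGT
CCAGGGAGACGGTGCGTCCGATATTTAATAACGCGAGAACGTGGCGAGCGTAATACAATCAGAGAGAGAA
GCGACGCATTCATTAGCACATGAATATGGAACGAAGAATCTCATATTAGGTCATTTCATCTCTTCGCACC
TACTAAACGGCCCATTGATGTAGAGCATAG
>AfrCa1b synthetic stand-in for GenBank PV125351
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTCAACAC
CACCATATAGAACAGAGTTTACCTCAACTGGTATCAGGGGAACAAGATTCCTTAAAAAATGTTAGTACGT
CCAGGGAGACGGTGCGTCCGATATTTAATAACGCGAGAACGTGGCGAGCGTAATACAATCGGAGAGAGAA
GCGACGCATTCATTAGCACATGAATATGGAACGAAGAATCTCATATTAGGTCATTTCATCTCTTCGCACC
TACTAAACGGCCCATTGATGTAGAGCATAG
>AfrCa1c synthetic stand-in for GenBank PV125352
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTCAACAC
CACCATATAGAACAGAGTTTACCTCAACTGGTATCAGGGGAACAAGATTCCTTAGAAAATGTTAGTACGC
CCAGGGAGACGGTGCGTCCGATATTTAATAACGCGAGAACGTGGCGAGCGTAATACAATCAGAGAGAGAA
GCGACGCGTTCATTAGCACATGAATATGGAACGAAGAATCTCATATTAGGTCATTTCATCTCTTCGTACC
TACTAAACGGCCCATTGATGTAGAGCATAG
>AfrCa1d synthetic stand-in for GenBank PV125358
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTCAACAC
CACCATATAGAACAGAGTTTACCTCAACTGGTATCAGGGGAACAAGATTCCTTAGAAAATGTCAGTACGT
CCAGGGAGACGGTGCGTCCGATATTTAATAACGCGAGAACGTGGCGAGCGTAATACAATCAGAGAGAGAA
GCGACGCATTCATTAGCACATGAATATGGAACGAAGAATCTCATATTAGGTCATTTCATCTCTTCGCACC
TACTAAACGGCCCATTGATGTAGAGCATAG
>AfrCa1e synthetic stand-in for GenBank PV125356
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTCAACAC
CACCATATAGAACAGAGTTTACCTCAACTGGTATCAGGGGAACAAGATTCCTTAGAAAATGTTAGTACGT
CCAGGGAGACGGTGTGTCCGATATTTAATAACGCGAGAACGTGGCGAGCGTAATACAATCAGAGAGAGAA
GCGACGCATTCATTAGCACATGAATATGGAACGAAGAATCTCATATTAGGTCATTTCATCTCTTCGCACC
TACTAAACGGTCCATTGATGTAGAGCATAG
>AfrCa1f synthetic stand-in for GenBank PV125357
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTCAACAC
CACCATATAGAACAGAGTTTACCTCAACTGGTATCAGGGGAACAAGATTCCTTAGAAAATGTTAGTACGT
CCAGGGAGACGGTGCGTCCGATATTCAATAACGCGAGAACGTGGCGAGCGTAATACAATCAGAGAGAGAA
GCGACGCATTCATTAGCACATGAATATGGGACGAAGAATCTCATATTAGGTCATTTCATCTCTTCGCACC
TACTAAACGGCCCATTGATGTAGAGCATAG
>AfrCa2a synthetic stand-in for GenBank PV125353
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTCAACAC
CACCATATAGAACAGAGTTTATCTCAATTGGTATCAGGGGAACAAGATTTCTTAGAAAATGTTAGTACGT
CCAGGGAGATGGTGCGTCCGATATTTAATAACGCGAGAATGTGGCGAGCGTAATACAATCAGAGAGAGAG
GCGACGCATTCATTAGCACATGAATATGGGACGAAGAATCTCATATTAGGTCATTTCATTTCTTCGCACC
TACTAAACGGCCCATTGATGTAGAGCATAG
>AfrCa2b synthetic stand-in for GenBank PV125354
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTCAACAC
CACCATATAGAACAGAGTTTATCTCAATTGGTATCAGGGGAACAAGATTTCTTAGAAAATATTAGTACGT
CCAGGGAGATGGTGCGTCCGATATTTAATAACGCGAGAATGTGGCGAGCGTAATACAATCAGAGAGAGAG
GCGACGCATTCATTAGCACATGAATATGGGACGAAGAATCTCATATTAGGCCATTTCATTTCTTCGCACC
TACTAAACGGCCCATTGATGTAGAGCATAG
>AfrCa2c synthetic stand-in for GenBank PV125355
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTCAACAC
CACCATATAGAACAGAGTTTATCTCAATTGGTATCAGGGGAACAAGATTTCTTAGAAAATGTTAGTACGT
CCAGGGAGATGGTGCGTCCGATATTTAATAACGCGAGAATGTGGCGAGCGTAATGCAATCAGAGAGAGAG
GCGACGCATTCATTAGCACATGAATATGGGACGAAGAATCTCATATTAGGTCATTTCATTTCTTCGCACC
TACTAAACGGCCCATTGATGTAGAGCATAG
>AfrRa1 synthetic stand-in for GenBank PV125359
GCCCTATCCTATAACTACGCATAAAAATTGTAATGTCCGGGATATGGGTTGTTTGCGAAAACCTCAATAC
CACCATATATAATAGAGTTTACCTCAACTGGTATCAGGGGAGCAAGATTCCCTAGAAAATGTTAGCACGT
CCAGGGAAACGGTGCGTCCGACATTTAATAACGTGAGAACGTGGCGAACGTAATACAATCAAAGAGAGAA
GCGACACATTCATTAGCACGTGAATATGGAACGGAGAATCTCATATTGGGTCATTTCATCTTTTCGCACC
TACTAGACGGCCCATTGATATAGAGCATAG
>AfrRa2 synthetic stand-in for GenBank PV125360
GCCCTATCCTATAACTACGCATAAAAATCGTAATGTCCGGGATGTGGGTTGTTTGCGAAAACCTTAATAC
CACCATATATAATAGAGTTTACCTCAACTGGTATCAGGGGAGCAAGACTCCCTAGAAAATGTTAGCACGT
CCAGGGAAACGGTGCGTCCGACATTTAGTAACGTGAGAACGTGGCGAACGTAATACAATCAAAGAGAGAA
GCGACACATTCGTTAGCACGTGAATATGGAACGGAGAATCTCATATTGGGTCATTTCATCTTTTCGCACC
TACTAGACGGCCCATTGGTATAGAGCATAG
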