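>seq0001
AGTGATTTATTACAGATATTCTCGGAGATCTGAGCATCAA
>seq0002
GGTGATCTAGCACAGATATTCTCGGAGATCTGAGCATTAA
>seq0003
GGTGATTTAGCCCAGATATTCCAGGAGACCTGAGCATCAA
>seq0004
AGTGATTTCTCACAGACATTCTCGGAGACCTGAGCATCAA
>seq0005
AGTGAATTAGTCCAGATATTGTCGGAGCTCTGAGCCTCAA
>seq0006
AGTGATCTAGCCCAGATATTCTCGGAGACCTGAGCATCAA
>seq0007
AGTGTTTTATTCCAAATATTCTAGGAGATCTGAGCATCAA
>seq0008
GGTGATTTCGCCCAGATATTCTCGGAGATCTGAGCATCAA
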