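>read_1
CCATGGGAG
>read_2
CATTAACCC
>read_3
TTTCCCGACGACGACT
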