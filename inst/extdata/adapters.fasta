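>TruSeq_R1 Illumina TruSeq adapter, read 1
AGATCGGAAGAGCACACGTCTGAACTCCAGTCA
>TruSeq_R2 Illumina TruSeq adapter, read 2
AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT
>Nextera Nextera transposase sequence
CTGTCTCTTATACACATCTCCGAGCCCACGAGAC
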