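>gliadin_26mer gamma-gliadin immunogenic 26-mer
FLQPQQPFPQQPQQPYPQQPQQPFPQ
>glia_qlq12
QLQPFPQPQLPY
>glia_pqp13
PQPQLPYPQPQLP
>glia_lgq19
LGQQQPFPPQQPYPQPQPF
>glia_33mer alpha-gliadin immunodominant 33-mer, (PQPQLPY)x3 core
LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF
>glia_omega26 omega-type repeat peptide, (PQQ)x2 blocks
FLQPQQPFPQQPQQPYPQQPQQPFPQ
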