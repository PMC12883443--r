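# toy three-gene model: A activates B, B inhibits C, C's logic unknown
A -> B
B -| C
C ->? A
$A: g_A(C)
$B: A
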