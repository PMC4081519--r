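# RGK motif patterns (PROSITE-like grammar: letters, [classes], x wildcard).
# signature: the C-terminal eleven-residue RGK signature (invariant Cys at -7)
signature [KR][SAF][KR][SH][C][HNED][DNEV][LM]x[VSA][L]
G1 GxxGxGKS
G3 DxWE
G4 NK
G5 ExSA
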