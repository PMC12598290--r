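FAM1 PGF 0 0 1 0
FAM1 PGM 0 0 2 0
FAM1 MGF 0 0 1 0
FAM1 MGM 0 0 2 0
FAM1 FATHER PGF PGM 1 0
FAM1 MOTHER MGF MGM 2 0
FAM1 CHILD FATHER MOTHER 2 0
FAM2 M2 0 0 2 0
FAM2 C2 0 M2 1 0
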