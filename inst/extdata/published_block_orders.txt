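# Locally-collinear-block orders of the ten compared plastomes, relative
# to the Balanops reference (identity, 13 blocks). One genome per line.
Balanops balansae: 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13
Balanops pedicellata: 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13
Lophopyxis maingayi: 1, 2, 3, 4, -6, -5, 7, 8, 9, 10, -13, 11, 12
Drypetes chevalieri: 1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12
Drypetes diopa: 1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12
Drypetes hainanensis: 1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12
Drypetes indica: 1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12
Drypetes lateriflora: 1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12
Drypetes longifolia: 1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12
Drypetes similis: 1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12
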