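MODEL        1
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O
ATOM      5  CA  GLY A   2       3.332   1.536   0.000  1.00  0.00           C
ENDMDL
MODEL        2
ATOM      1  N   ALA A   1       0.100   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.558   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.109   1.420   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       1.351   2.390   0.000  1.00  0.00           O
ATOM      5  CA  GLY A   2       3.432   1.536   0.000  1.00  0.00           C
ENDMDL
MODEL        3
ATOM      1  N   ALA A   1       0.200   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.658   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.209   1.420   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       1.451   2.390   0.000  1.00  0.00           O
ATOM      5  CA  GLY A   2       3.532   1.536   0.000  1.00  0.00           C
ENDMDL
END
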