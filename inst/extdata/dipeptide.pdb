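ATOM      1  N   GLY A   1      -1.458   0.000   0.000  1.00  0.00           N
ATOM      2  H   GLY A   1      -1.968   0.870   0.000  1.00  0.00           H
ATOM      3  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C
ATOM      4  C   GLY A   1       0.551   1.420   0.000  1.00  0.00           C
ATOM      5  O   GLY A   1      -0.200   2.400   0.050  1.00  0.00           O
ATOM      6  N   GLY A   2       1.870   1.580   0.000  1.00  0.00           N
ATOM      7  CA  GLY A   2       2.500   2.890   0.050  1.00  0.00           C
ATOM      8  C   GLY A   2       4.010   2.750   0.100  1.00  0.00           C
ATOM      9  O   GLY A   2       4.600   1.690   0.150  1.00  0.00           O
ATOM     10  OXT GLY A   2       4.680   3.800   0.120  1.00  0.00           O
END
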