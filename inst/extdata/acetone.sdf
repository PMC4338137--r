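acetone
  synthetic 3D coordinates

  4  3  0  0  0  0  0  0  0  0999 V2000
   -1.2900    0.1000    0.2000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8000    1.2800    0.1000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5800   -1.1000   -0.2000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  2  4  2  0
M  END
$$$$
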