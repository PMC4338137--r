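benzene
  synthetic 3D coordinates

  6  6  0  0  0  0  0  0  0  0999 V2000
    1.3900    0.0000    0.1000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6950    1.2037    0.1500 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6950    1.2037    0.1000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3900    0.0000    0.0500 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6950   -1.2037    0.1000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6950   -1.2037    0.1500 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
M  END
$$$$
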