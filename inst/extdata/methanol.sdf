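methanol
  synthetic 3D coordinates

  3  2  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4000    0.0000    0.3000 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.9000    0.8000    0.1000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
M  END
$$$$
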