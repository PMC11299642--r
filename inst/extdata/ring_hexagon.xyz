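6
synthetic planar aromatic-sized hexagon, angstroms
C     1.39000000       0.00000000       0.00000000  C1
C     0.69500000       1.20377670       0.00000000  C2
C    -0.69500000       1.20377670       0.00000000  C3
C    -1.39000000       0.00000000       0.00000000  C4
C    -0.69500000      -1.20377670       0.00000000  C5
C     0.69500000      -1.20377670       0.00000000  C6
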