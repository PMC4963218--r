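Synthetic GIAO shielding job output (text fixture)
 SCF Done:  E(RB98) =  -1234.56789
 Magnetic shielding tensor (ppm):
      1  C    Isotropic =   158.4521   Anisotropy =    25.1034
      2  C    Isotropic =    21.8812   Anisotropy =    12.4450
      3  N    Isotropic =   201.3377   Anisotropy =    40.9921
 End of shielding computation.
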