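{
  "description": "Additive 13C shift effects of modification states (ppm, shift space) with zero-sum per-rotamer offsets. Anchor 'calibrated' marks entries set to published mean Delta values for Lys validation data; 'illustrative' marks defaults chosen to emulate figure-level separations only and intended to be overridden by users with their own shielding computations.",
  "entries": [
    {"residue": "LYS", "state": "charged", "nucleus": "CE", "effect": 0.0,
     "rotamer_offsets": {"-": 0.0}, "anchor": "calibrated",
     "note": "unmodified reference state; Delta centered at zero by construction"},
    {"residue": "LYS", "state": "acetyl", "nucleus": "CE", "effect": 1.5,
     "rotamer_offsets": {"0": 1.3, "180": -1.3}, "anchor": "calibrated",
     "note": "published mean Delta of the Lys 13C-epsilon shift upon N-zeta acetylation"},
    {"residue": "LYS", "state": "monomethyl", "nucleus": "CE", "effect": -10.1,
     "rotamer_offsets": {"60": 1.95, "-60": -1.95, "180": 0.0}, "anchor": "calibrated",
     "note": "published mean Delta of the Lys 13C-epsilon shift upon mono-methylation"},
    {"residue": "LYS", "state": "dimethyl", "nucleus": "CE", "effect": -19.1,
     "rotamer_offsets": {"60": 1.95, "-60": -1.95, "180": 0.0}, "anchor": "calibrated",
     "note": "published mean Delta of the Lys 13C-epsilon shift upon di-methylation"},
    {"residue": "LYS", "state": "trimethyl", "nucleus": "CE", "effect": -25.8,
     "rotamer_offsets": {"-": 0.0}, "anchor": "calibrated",
     "note": "published mean Delta of the Lys 13C-epsilon shift upon tri-methylation"},
    {"residue": "ARG", "state": "charged", "nucleus": "CZ", "effect": 0.0,
     "rotamer_offsets": {"-": 0.0}, "anchor": "calibrated",
     "note": "unmodified reference state"},
    {"residue": "ARG", "state": "monomethyl-NE", "nucleus": "CZ", "effect": -2.5,
     "rotamer_offsets": {"-": 0.0}, "anchor": "illustrative",
     "note": "order of magnitude consistent with the mono-methyl Arg 13C-zeta separation"},
    {"residue": "ARG", "state": "monomethyl-NH", "nucleus": "CZ", "effect": -2.5,
     "rotamer_offsets": {"NH1:0": 0.65, "NH1:180": -0.65, "NH2:0": 0.65, "NH2:180": -0.65},
     "anchor": "illustrative",
     "note": "mono-methylation at either N-eta; indistinguishable from N-epsilon methylation in shift"},
    {"residue": "ARG", "state": "dimethyl-sym", "nucleus": "CZ", "effect": -5.5,
     "rotamer_offsets": {"0": 0.65, "180": -0.65}, "anchor": "illustrative",
     "note": "symmetric di-methylation; overlaps asymmetric form"},
    {"residue": "ARG", "state": "dimethyl-asym", "nucleus": "CZ", "effect": -5.5,
     "rotamer_offsets": {"NH1:a": 0.65, "NH1:b": -0.65, "NH2:a": 0.65, "NH2:b": -0.65},
     "anchor": "illustrative",
     "note": "asymmetric di-methylation; overlaps symmetric form"},
    {"residue": "SER", "state": "unmodified", "nucleus": "CB", "effect": 0.0,
     "rotamer_offsets": {"-": 0.0}, "anchor": "calibrated", "note": "unmodified reference state"},
    {"residue": "SER", "state": "GalNAc-alpha", "nucleus": "CB", "effect": -4.0,
     "rotamer_offsets": {"-": 0.0}, "anchor": "illustrative",
     "note": "O-linked alpha-GalNAc on Ser; overlaps beta-GlcNAc form"},
    {"residue": "SER", "state": "GlcNAc-beta", "nucleus": "CB", "effect": -4.0,
     "rotamer_offsets": {"-": 0.0}, "anchor": "illustrative",
     "note": "O-linked beta-GlcNAc on Ser; overlaps alpha-GalNAc form"},
    {"residue": "THR", "state": "unmodified", "nucleus": "CB", "effect": 0.0,
     "rotamer_offsets": {"-": 0.0}, "anchor": "calibrated", "note": "unmodified reference state"},
    {"residue": "THR", "state": "GalNAc-alpha", "nucleus": "CB", "effect": 5.0,
     "rotamer_offsets": {"-": 0.0}, "anchor": "illustrative",
     "note": "O-linked alpha-GalNAc on Thr; well separated from the unmodified form"},
    {"residue": "THR", "state": "GlcNAc-beta", "nucleus": "CB", "effect": 0.5,
     "rotamer_offsets": {"-": 0.0}, "anchor": "illustrative",
     "note": "O-linked beta-GlcNAc on Thr; strongly overlaps the unmodified form"},
    {"residue": "ASN", "state": "unmodified", "nucleus": "CG", "effect": 0.0,
     "rotamer_offsets": {"-": 0.0}, "anchor": "calibrated", "note": "unmodified reference state"},
    {"residue": "ASN", "state": "GlcNAc-beta", "nucleus": "CG", "effect": 3.0,
     "rotamer_offsets": {"-": 0.0}, "anchor": "illustrative",
     "note": "N-linked beta-GlcNAc on Asn"}
  ]
}
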