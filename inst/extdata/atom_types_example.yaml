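# Atom-type table: per-type partial charge (e), self 12-6 coefficients
# (kcal*A^12/mol, kcal*A^6/mol) and polarizability (A^3).
atom_types:
  M2p:              # divalent metal cation
    Q: 2.0
    C12: 135000.0
    C6: 120.0
    alpha0: 0.29
  o:                # deprotonated phosphate oxygen
    Q: -0.9
    C12: 590000.0
    C6: 600.0
    alpha0: 2.5
  OW:               # water oxygen
    Q: -0.834
    C12: 581935.6
    C6: 594.8
    alpha0: 1.44
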