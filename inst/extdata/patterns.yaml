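# Motif patterns.  The yeell entry is the 21-residue CTL consensus with the
# 5-residue Y-E-E-L-L core (pattern positions 5-9).  gld / gld_like are
# placeholders: their full residue composition is published only as sequence
# LOGOs, so replace them with real patterns if ATL/BTL motif evidence is
# wanted.
- name: yeell
  consensus: "(D/E/V)XX(S/T/N)(Y/F)E(E/Q/A)(L/M)(L/T/I)XLX(E/D/N)X(L/I/M)GX(V/A/E)XX(G/A/R)"
  core: [5, 9]
  max_mismatch: 3
- name: gld
  consensus: "GLD"
  max_mismatch: 0
- name: gld_like
  consensus: "GDL"
  max_mismatch: 0
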