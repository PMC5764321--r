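# Lineage spacing profiles for the RING-H2 grammar (gaps g1..g7 are the
# residue counts strictly between consecutive metal ligands).
- name: canonical
  spacing_min: [2, 14, 2, 2, 2, 10, 2]
  spacing_max: [2, 14, 2, 2, 2, 10, 2]
  canonical_spacing: [2, 14, 2, 2, 2, 10, 2]
- name: fungal
  spacing_min: [2, 15, 2, 2, 2, 11, 2]
  spacing_max: [2, 15, 2, 2, 2, 11, 2]
  canonical_spacing: [2, 15, 2, 2, 2, 11, 2]
- name: kinetoplast
  spacing_min: [2, 14, 2, 2, 2, 10, 2]
  spacing_max: [2, 40, 2, 2, 2, 10, 2]
  canonical_spacing: [2, 14, 2, 2, 2, 10, 2]
- name: ciliate
  spacing_min: [2, 14, 2, 2, 2, 10, 2]
  spacing_max: [2, 40, 2, 2, 2, 10, 2]
  canonical_spacing: [2, 14, 2, 2, 2, 10, 2]
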