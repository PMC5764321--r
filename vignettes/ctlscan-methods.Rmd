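---
title: "Methods: RING-H2 grammar, YEELL scanning and CTL family calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RING-H2 grammar, YEELL scanning and CTL family calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlscan)
```

## The model

`ctlscan` treats RING-domain detection as a **position grammar**: a RING-H2
domain is any placement of eight metal-ligand residues (C,C,C,H,H,C,C,C;
the fifth position also admits C, which types the placement RING-HC) whose
seven inter-ligand gaps fall in per-lineage ranges. This is deliberately not
an HMM or PSSM: the family-defining observations are about exact ligand
classes and exact spacings, and a grammar makes every accept/reject decision
auditable.

The canonical gap vector is **(2, 14, 2, 2, 2, 10, 2)**. Only the second gap
(fourteen residues between ligands 2 and 3) is strongly lineage-diagnostic;
g1 and g7 are the universal C-x2-C bookends of RING domains and the
remaining gaps are the generic RING envelope. Because the full vector is not
uniquely determined by published alignments, all seven values are
configurable per profile (`lineage_profile()`, YAML via `load_profiles()`).
Four profiles ship:

| profile | g2 | g6 | rationale |
|---|---|---|---|
| canonical | 14 | 10 | plants, vertebrates, invertebrates |
| fungal | 15 | 11 | exactly one extra residue at each |
| kinetoplast | 14–40 | 10 | up to 26 extra residues at g2 |
| ciliate | 14–40 | 10 | as kinetoplast |

The kinetoplast range starts at 14 (insert 0) rather than 15: observed
kinetoplast domains carry 1–26 extra residues, but a profile whose reference
spacing lies outside its own acceptance range would be internally
inconsistent, and accepting the canonical spacing is harmless for a
fail-open scanner.

**Overlap resolution.** All candidate placements are enumerated, then
accepted greedily: leftmost start first, ties broken by minimal total
absolute insert, then lexicographically smallest ligand tuple; an accepted
hit blocks any candidate sharing one of its ligand positions. This makes the
hit list deterministic and byte-identical across runs.

**Diagnostics.** ATL is marked by Leu at ligand2+1, Arg at ligand3−4 and Asp
at ligand6+1; BTL by Pro at ligand6+2. The conserved proline near the third
ligand is reported on the *upstream* side (ligand3−1 `adjacent`, ligand3−2
`separated_by_one`): published alignments do not state the side explicitly,
so the upstream reading is a package choice and the flag is informational
only — no family rule consumes it.

## Motif scanning

The YEELL consensus is a 21-position degenerate pattern with 13 constrained
positions and 8 wildcards; its 5-residue core (pattern positions 5–9) reads
Y-E-E-L-L through the primary residue of each constrained set. Scanning
slides the pattern over every window and counts mismatches at constrained
positions only; wildcards never match or mismatch, and `X` in a sequence
always mismatches. The default budget of **3 mismatches** keeps ≥ 10/13 ≈
77% of constrained positions matched, consistent with the ~75% per-position
conservation that defined the motif; whether that figure describes
per-position conservation or per-sequence presence is ambiguous in the
source, so the budget interpretation is an explicit, configurable choice.

GLD and GLD-like (the ATL/BTL upstream motifs) ship only as placeholders:
their residue composition is published as sequence LOGOs, not text, so users
must supply real patterns if that evidence is wanted.

**Chou–Fasman.** The helix check uses the classic nucleation/extension
scheme with the original propensity table: nucleate any 6-residue window
with ≥ 4 residues of Pα > 1.03, extend while the advancing 4-residue edge
keeps mean Pα ≥ 1.00, merge, and keep segments with mean Pα > mean Pβ. The
reference analysis used a commercial implementation whose constants are not
published; these values are the textbook ones and all are arguments of
`chou_fasman_helix()`. A motif is "in helix context" if a predicted segment
covers ≥ 50% of its length.

## Family calling

`classify_proteome()` applies the first matching rule:

1. no RING-H2 → **none**;
2. YEELL within budget, strictly upstream of ligand 1, gap ≤ 150 → **CTL**;
3. ≥ 2 of 3 ATL diagnostics → **ATL**;
4. BTL Pro diagnostic → **BTL**;
5. YEELL upstream at budget + 2 → **CTL-like**;
6. otherwise **RING-H2-unclassified**.

Choices worth defending:

* **CTL precedes the residue diagnostics** because motif co-occurrence is
  the family-defining criterion; diagnostic residues are characteristic, not
  exclusive.
* **ATL needs 2 of 3 flags**, not all 3 — the diagnostics are described as
  restricted to ATLs, not as universally present in them. Configurable via
  `classify_params(atl_min_flags=)`.
* **Upstream window 150 residues**: the motif sits "next to" the domain in
  every depicted protein but no maximum gap is printed; 150 comfortably
  covers the depicted spacings while excluding motifs in a distant
  N-terminal domain. Configurable.
* **CTL-like budget = budget + 2** operationalises the Basidiomycota
  observation of degraded, non-qualifying YEELL-region similarity.
* With several RING-H2 hits the call is made against the hit with the most
  evidence (qualifying upstream motif, then diagnostic count, then leftmost)
  and the choice is logged.

## Phylogeny

Domains are aligned by their anchors: ligand columns are fixed and each
spacer block is right-padded with gaps to the widest member, so degapping
recovers every input domain exactly. This replaces a general aligner, which
would be overkill for domains already matched by a common grammar, and makes
distances deterministic.

Distances are pairwise-deletion p-distances (columns with a gap in either
row are skipped for that pair), optionally Poisson-corrected
(d = −ln(1 − p)). Neighbor-Joining is implemented in the package because its
required contracts — Q-criterion, ties broken by the smallest (i, j) pair in
the current matrix, negative branch lengths clamped to zero with a warning —
are part of the specification of the method here; `ape::nj` serves as an
independent cross-check in the tests, and on additive matrices both recover
the generating tree exactly (the package's NJ to < 1e−9, verified against
brute-force topology enumeration at small n). Bootstrap resamples alignment
columns with replacement; support of an internal edge is the fraction of
replicate trees containing its bipartition.

Group assignment mirrors the A–H grouping of plant CTLs: each leaf takes the
group of its nearest anchor by path length, and a leaf whose best
other-group anchor is within 10% (relative) of its nearest anchor is deemed
ambiguous and assigned **H**. The source grouped incongruent external
branches into H by visual inspection; the margin rule is the package's
operational stand-in and is configurable.

## Gene architecture

Models are read from GFF3 (one model per mRNA, `Parent`-linked). All
coordinates are **1-based inclusive throughout** — the GFF3 and Bioconductor
convention — so no boundary conversion exists to get wrong; minus-strand
segment lists are ordered 5′→3′ in transcript orientation and every report
is strand-invariant. The 5′UTR is always derived as the exon parts strictly
5′ of the first coding base, making models comparable whether or not the
annotation carries explicit UTR features.

CDS introns are gaps between consecutive CDS segments; 5′UTR introns are
gaps between consecutive 5′UTR parts. An intron falling exactly at the
UTR/CDS boundary is therefore counted in neither list — a rare edge the
source never defines. `splice_in_motif()` maps protein residue i to CDS
nucleotides 3(i−1)+1..3i and reports whether any CDS junction lies strictly
inside the motif's nucleotide span, which is how the conserved splice site
inside YEELL is checked.

## What the synthetic generator does and does not emulate

`generate_proteome()` builds each protein as flank + (YEELL instance) +
linker + RING-H2 domain, with diagnostic sites pinned per label and every
random segment drawn from a configurable background (uniform over the 20
residues by default). Assembled proteins are rejection-sampled against the
package's own scanners so that exactly the planted structure is recoverable —
truth labels are exact by construction, which is what makes 100%
precision/recall at mutation rate 0 a meaningful integrity check rather than
an empirical claim. Flank lengths default to 60–100 residues and linkers to
20–40, matching the compact N-termini and short motif-to-domain spacings of
depicted CTLs; mutation controls plant a fixed number of constrained-motif
or ligand mutations per sequence.

The generator deliberately does **not** emulate: indels, tree-structured
evolution (sequences are i.i.d. given their label), compositional bias,
multi-domain architectures, or degraded motifs at intermediate divergence.
Passing tests therefore demonstrate that the computation is correct and
self-consistent, not that real proteomes are classified with these error
rates: real recall depends on how far real family members stray from the
consensus, which only curated data can calibrate.

## Numerical choices and problem sizes

Determinism is enforced everywhere: all generators take explicit seeds and
restore the caller's RNG state; scans and classifications are pure. The test
and acceptance workloads use 50 proteins per label (500 for the mutated-CTL
recall estimate), 100 random additive matrices of 4–8 taxa with brute-force
topology enumeration on the n ≤ 6 cases, and 100-replicate bootstraps —
sizes at which every stochastic check is stable across seeds while the full
suite runs in about a minute.

## Known limitations

* The grammar requires all eight ligands; a domain with a mutated ligand is
  invisible rather than reported as damaged.
* Diagnostic flags are single-residue checks; no weighting or PSSM.
* NJ is the only tree method; no ML/MP, no substitution matrices beyond
  p/Poisson, no rooting.
* ATL transmembrane helices and the BTL BZF finger are out of scope; calls
  rest on RING diagnostics and motifs only.
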