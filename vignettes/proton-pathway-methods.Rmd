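---
title: "Tracing proton transfer pathways: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing proton transfer pathways: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A proton transfer pathway (PTP) is modelled as a chain of relay sites —
side chains able to donate/accept protons or form hydrogen bonds —
linking a buried anchor (here, the azadithiolate bridgehead amine of an
[FeFe] hydrogenase H-cluster, or any user-supplied atom or 3-D point) to
the solvent. The search is purely geometric:

* **Relay eligibility.** A residue contributes a relay site when its type
  has candidate side-chain N/O/S heavy atoms in the relay table:
  carboxylates (Asp OD1/OD2, Glu OE1/OE2), His ring nitrogens, Lys NZ,
  Arg NE/NH1/NH2, Cys SG and Tyr OH as *protonatable*; Ser OG and Thr OG1
  as *hydroxyl_polar*; Asn/Gln amide atoms as *amide_polar*; the water
  oxygen as *water*. Backbone amides/carbonyls and Trp NE1 are never
  relays. Hydrogens are parsed but ignored: all distances are between
  heavy atoms.
* **Distance convention.** The distance between two sites is the minimum
  Euclidean distance over all pairs of their relay atoms (the anchor
  contributes a single point). Published pathway figures quote one
  distance per residue pair without naming atoms; min-over-pairs is the
  reproducible choice and the realising atom pair is always reported.
* **Greedy outward trace.** From the anchor, the nearest unvisited
  eligible site within the cutoff is accepted, and the walk continues
  from it. This mirrors the stepwise outward screen such pathways are
  found by, rather than a global optimisation; the exhaustive enumerator
  (`enumerate_pathways()`) exists precisely to audit the greedy choice on
  small structures.
* **Adaptive cutoff.** The base cutoff is `d0 = 5.0` Å — "around 5 Å" is
  the screening range within which a relay pair could be bridged directly
  or via an unresolved water. If no candidate qualifies, the cutoff grows
  in `step = 0.1` Å increments to at most `dmax = 5.3` Å, and is reset to
  `d0` after every accepted relay, so the extension stays a local rescue
  rather than a global loosening. Each accepted step records
  `cutoff_used`, the first level `d0 + k·step` (capped at `dmax`) at or
  above its distance.
* **Surface criterion.** A residue is surface-exposed when its relative
  side-chain accessibility reaches `sasa_threshold = 0.20` — the
  conventional exposed/buried boundary for relative SASA. Accessibility
  is side-chain SASA divided by the residue's standard-state side-chain
  maximum from Miller, Janin, Lesk & Chothia (1987) J Mol Biol 196:641
  (Gly-X-Gly values: ALA 67, ARG 196, ASN 113, ASP 106, CYS 104, GLN 144,
  GLU 138, HIS 151, ILE 140, LEU 137, LYS 167, MET 160, PHE 175, PRO 105,
  SER 80, THR 102, TRP 217, TYR 187, VAL 117 Å²; water is assigned its
  free-sphere area 4π(1.52+1.4)² ≈ 107.1 Å²; Gly, having no side chain,
  gets relative accessibility 0). Ratios are clipped to [0, 1.2]: an
  isolated residue exceeds the tripeptide-context maximum slightly.

### SASA computation

Shrake–Rupley point sampling with a deterministic golden-spiral point set
(no RNG, so results are bit-stable), 960 points per atom by default,
probe radius 1.4 Å, van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20, Fe 2.00 Å (overridable, unknown elements are an error). A sample
point on an atom's solvent-accessible sphere counts as exposed when it
lies outside every neighbour's accessible sphere. Convergence is asserted
as agreement of per-atom *exposed fractions* (area divided by the full
accessible-sphere area) between 960 and 3840 points to better than 3
percentage points; a plain ratio is not a meaningful convergence measure
for atoms whose exposure is a sliver of the sphere.

### Tie-breaking and degenerate inputs

Candidate distances equal within 1 µÅ order by lower residue number, then
chain id — reproducibility, not physics. Structures with zero eligible
sites give an empty pathway with status `exhausted_cutoff`; `max_steps`
(default 20) guards against pathological walks. Alternate locations
resolve to the highest occupancy (ties: lexicographically first altloc);
only the first MODEL of multi-model files is used. Waters are excluded by
default because homology models typically lack intraprotein waters;
`include_waters` admits them for crystal structures. Asn/Gln amides are
tabulated but excluded from the default eligible classes
(`protonatable`, `hydroxyl_polar`): whether an amide can relay a proton
is mechanism-dependent, and the class can be switched on per run.
Display distances round to one decimal with round-half-even; JSON output
keeps full precision.

## Conservation analysis

Each phylogenetic group is one alignment; all groups must share a column
coordinate system (per-group subsets of a master alignment, or
equal-length alignments). The reference sequence (e.g. the protein whose
numbering positions like E252 are quoted in) lives in the target group;
its k-th non-gap column defines reference position k.

Column frequencies exclude gaps and `X` from the denominator (both count
into the gap fraction). Information content is the Schneider–Stephens
form IC = log2 20 − H without small-sample correction (group sizes in
such datasets are large; a correction flag would bias comparisons between
groups of different size more than it helps). "Normalised" logo letter
heights are f · IC · (1 − gap fraction), i.e. occupancy-weighted —
rendering conventions for consensus logos differ between tools, so the
definition used here is declared rather than claimed identical to any
particular viewer.

A position is *exclusive* to the target group when its consensus fraction
is ≥ `c_high = 0.9` there while every other group either stays below
`c_high` or holds a different consensus residue; the score is the
target's consensus fraction minus the largest frequency of that same
residue elsewhere. `c_high = 0.9` operationalises "highly conserved" and
0.5 "moderately conserved"; both are reported alongside every call.
A shared conserved residue (the situation of the glutamate that Group A
and Group D hold in common) is therefore never exclusive, by
construction. The hydroxyl fraction f(S) + f(T) captures positions
conserved as a chemical class rather than as one residue.

## What the synthetic generators emulate

`generate_relay_structure()` plants relay side chains along a gentle
outward arc (20° turn per step) at exact spacings — by default
3.4 / 3.5 / 4.1 / 5.2 Å, the distances of the proposed Group D chain,
with the last hop deliberately beyond the base cutoff so recovery
exercises the adaptive extension. Carboxylate residues carry both oxygens
(the second offset 2.2 Å perpendicular to the local path direction,
alternating sides) so the min-over-pairs distance equals the planted
primary spacing exactly; the generator asserts this before returning.
Hydrophobic decoys (Ala/Val/Leu, no relay atoms) fill a 6 Å shell around
the chain by Poisson-disk rejection sampling (3.0 Å minimum separation,
≥ 2.8 Å from relay atoms), burying the anchor end; an open half-space
plus a 4.5 Å exclusion ball keep the terminal relay solvent-exposed. A
hetero group supplies the anchor nitrogen and an iron analog 2.5 Å away.
`jitter` displaces every atom in a uniformly random direction by a
magnitude drawn uniformly from [0, jitter] — i.e. it is the maximum
displacement in Å, a bounded perturbation chosen so that "0.1 Å jitter"
means what it says for every atom.

What the generator does **not** emulate: real backbone connectivity,
rotamer geometry, packing quality, waters, or crystallographic noise
models. Passing the planted-recovery tests therefore shows the search
machinery is correct under controlled geometry; it does not show that a
5.0/5.3 Å screen is chemically sufficient on any particular real
structure — for that, the pipeline must be run on an actual model, and an
external check on a Group A crystal structure plus a Group D homology
model (expecting the E252 → E289 → S249 → D265 chain) is the natural
validation route when such a model is available.

`generate_group_msas()` draws background columns i.i.d. (uniform over the
20 amino acids by default) and planted columns at a controlled consensus
probability in designated groups; several residues planted on one column
partition the probability space jointly (p₁ for the first, p₂ for the
second, …). The reference is the target group's first sequence with the
planted residues forced, so every planted column is addressable in
reference numbering. Real alignments differ in having phylogenetic
correlation between sequences, gaps, and non-uniform background
composition — so the planted-recovery rates measured here are an upper
bound on what correlated real data would give.

## Validation problem sizes

The test suite validates: exact recovery of the default planted chain
(204 atoms); greedy-vs-brute-force step distances and membership in the
exhaustive enumeration over 100 random screening structures (12–26
residues each, 16 Å box); cutoff boundary behaviour at 5.15 / 5.2 /
5.35 Å; the analytic sphere area of an isolated oxygen and a 20-atom
cage; information-content closed forms to 1e-9; exclusivity recovery on
four groups × 50 sequences × 200 columns with 20 planted columns at
p = 0.95 (at that sample size the realised consensus fraction of a
planted column falls below the 0.9 call threshold with probability
≈ 2–3%, so recall is expected near, not at, 1); and planted-chain
recovery under 0.1 Å jitter across 50 seeds, where the 5.2 Å terminal
hop sits 0.1 Å under `dmax` and bounded jitter of 0.1 Å can occasionally
push it over — the bounded jitter model keeps that failure rate to a few
percent of seeds. These sizes keep the whole suite around a minute on one
CPU while exercising every contract.

## Known limitations

* Distance-only hydrogen-bond criterion: no donor–acceptor angles, no
  energetics, no pKa or protonation-state reasoning.
* Greedy traversal can in principle diverge from a globally optimal
  chain; the enumerator bounds this audit to ≤ 40 eligible sites.
* Relative-SASA surface detection depends on the reference maxima chosen;
  the Miller set is recorded verbatim and swappable.
* PDB only (fixed-width ATOM/HETATM); mmCIF, assemblies and anisotropic
  records are out of scope.
* Alignment construction, structural superposition and homology modelling
  are upstream; the package consumes their outputs.
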