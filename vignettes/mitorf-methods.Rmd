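---
title: "Methods: divergence analysis of the mitochondrial release-factor paralogs"
author: "mitorf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence analysis of the mitochondrial release-factor paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorf)
```

## Background and scope

Vertebrate mitochondria use a reduced stop-codon repertoire: UGA is
reassigned to tryptophan, leaving UAA and UAG as the standard stops
(vertebrate mitochondrial genetic code, translation table 2). The
canonical mitochondrial release factor mtRF1a recognises these codons in
the ribosomal A-site; its vertebrate-specific paralog mtRF1 shows no
release activity on any tested codon. `mitorf` implements the
computational analyses that characterise this divergence and its
structural consequences: where the paralogs differ, how those
differences remodel the codon-reading head and the switch loop, which
decoding-center conformations a posed mtRF1 model can physically
coexist with, and whether mtRF1a alone suffices to terminate every
mitochondrial open reading frame.

The package consumes finished inputs — precomputed alignments, posed
coordinate models, annotated genomes. Alignment computation, homolog
searching, phylogenetics and homology-model building are out of scope.

## Subfamily-discriminating positions

For a two-subfamily labeled alignment, `detect_discriminating_positions()`
applies a strict conservation criterion per column: every member of
subfamily A carries one identical residue, every member of subfamily B
carries one identical residue, and the two residues differ. Three
deliberate tightenings:

* a gap anywhere inside a subfamily disqualifies the column for that
  family — columns that are *all*-gap in one family are the signature of
  a subfamily-specific insertion and are routed to
  `detect_insertions()` instead, so substitutions and insertions are
  reported separately;
* ambiguity codes (X, B, Z, J) never count as conserved;
* input is case-insensitive and `-`/`.` are both read as gaps.

`detect_insertions()` reports maximal runs of columns all-gap in one
family and majority-residue (more than half non-gap) in the other, with
the per-column majority consensus of the carrying family (alphabetical
tie-break) and the last reference position before the run as anchor.

Positions are mapped to reference numbering by
`map_to_reference()`: the 1-based count of non-gap reference characters
up to the column, or `"anchor+offset"` inside reference gaps. Columns
are 1-based throughout, following R convention. The mapping is
non-decreasing in the column index by construction.

`pairwise_identity()` needs a stated convention to be reproducible:
identity = 100 × (identical pairs) / (jointly non-gap columns), rounded
to the nearest integer. The denominator choice (not alignment length,
not the shorter sequence) is a documented package decision.

## Geometry primitives

`read_structure()` parses fixed-column PDB via bio3d, keeping ATOM and
HETATM records, resolving alternate locations to the highest-occupancy
conformer (ties to altloc A) and keeping insertion codes as part of
residue identity. Residue numbers follow the file's author numbering;
all release-factor positions quoted here are in *T. thermophilus* RF1
numbering.

**Hydrogen bonds** (`detect_hbonds()`). Donor/acceptor roles come from
an embedded chemistry table: protein backbone N (donor, except proline)
and O/OXT (acceptor), side-chain donors/acceptors per residue type, and
nucleotide base/ribose/phosphate N and O by standard atom name. A pair
is a bond when the heavy-atom distance lies in [2.4, 3.5] Å; the
D–H···A angle cutoff (120°) applies only when hydrogens are present on
the donor, because crystal structures and models at this resolution
generally lack them. Pairs within one residue are excluded.

**Steric clashes** (`detect_clashes()`). Van der Waals radii C 1.70,
N 1.55, O 1.52, P 1.80, S 1.80, H 1.10 Å; a pair clashes severely when
the overlap `r_a + r_b − d` exceeds 0.4 Å. The 0.4 Å threshold is the
widely used crystallographic convention, configurable because it is a
convention rather than a measured quantity. Same-residue pairs and
covalently bonded inter-residue neighbours (peptide C–N, nucleic
O3'–P) are excluded.

**Superposition** (`superpose()`). Least-squares rigid fit by the
Kabsch/SVD construction with the reflection branch removed
(determinant +1 enforced), returning rotation, translation and post-fit
RMSD. Degenerate correspondences (< 3 pairs, collinear references) are
rejected. The tests cross-check the RMSD against an independent
quaternion (Horn) fitter.

The switch-loop proximity quoted as 3.7 Å is measured from the Thr-295
backbone carbonyl **oxygen atom** to all atoms of A-1493 — measuring to
the oxygen alone (not the C=O group) is a recorded package choice.

## Regions and the divergence report

The release-factor fold is described by a `region_table()`: four
domains, the switch loop, the recognition loop, the helix α5 tip and
helix α7, plus the GGQ and PXT motif positions. Only the switch loop
interval [286, 301] is fixed by the literature; the domain boundaries
(domain 1 [1, 108], domain 2 [109, 205], domain 3 [206, 285], domain 4
[302, 360]) are editorial defaults derived from the four-domain RF1
topology and are plainly overridable configuration.

For counting, each position gets a single primary region. The switch
loop takes precedence over its flanking domains; the recognition loop
and helix tips do **not** take precedence over domain 2 — they are
annotation, and their positions (e.g. the PXT motif at 184–186) count
with the codon-recognition domain. This is the design choice that makes
the canonical partition come out as 20 positions in domain 2, 2 in the
switch loop, 1 each in domains 1 and 3; giving the recognition loop
precedence would instead split domain 2's count, contradicting the
published partition style. Full label sets are still reported per
position, and totals over the primary assignment always sum to the
input count.

`clustering_pvalue()` quantifies spatial clustering of a residue set:
statistic = mean pairwise Cα distance, null = same-size uniform residue
subsets of the same chain, and the add-one permutation estimator
`p = (1 + #{null ≤ observed}) / (1 + N)`, which is never zero and equals
1 when the set is the whole chain.

## Decoding-center states and binding compatibility

The decoding nucleotides A-1492/A-1493 adopt distinct conformations:
stacked within their helix (empty A-site), flipped out against a
cognate codon–anticodon helix (unstacked), or the stop-codon-recognized
arrangement that contacts the release-factor switch loop.
`classify_decoding_state()` superposes the invariant local rRNA frame
(G-1491/U-1494 in the shipped templates) onto each labeled template and
returns the label with the smallest RMSD over the A-1492/A-1493 base
ring atoms, breaking ties in the order stacked < unstacked <
recognized.

The shipped templates (`decoding_center_templates()`) are **synthetic
idealized constructs built in code** — three well-separated rigid
arrangements of idealized adenine rings on a common frame — not
extracts of experimental structures. For experimental work the
templates argument accepts models prepared from the corresponding PDB
entries; the classifier itself is agnostic.

`binding_compatibility()` renders the central verdict: a release-factor
pose is compatible with a decoding-center state iff it makes no severe
clash with the decoding nucleotides (A-1492, A-1493, helix-69 A-1914).
In the mtRF1 fixture the RT-insert arginine (R-RTi, residue 115A)
occupies exactly the recognized-state position of A-1493, so the
verdict flips from compatible (stacked, empty A-site) to incompatible
(recognized). The verdict is monotone in the clash threshold by
construction. One caveat is recorded here: the unstacked (cognate
tRNA) state is also classified, but its biological incompatibility with
release-factor binding comes from the mRNA/tRNA occupying the A-site,
which is outside the modeled atom set; the package reports what the
atoms present can show.

`switch_loop_interactions()` inventories hydrogen bonds of switch-loop
residues, labeling partners as `decoding_center`, `insert`,
`helix_capping` (partners at the α7-capping positions 298/301) or
`intramolecular`; loop-internal bonds are inventoried only when one
side is a capping position. `interaction_replacement()` compares two
inventories position-by-position — the canonical use is showing the
A-1493 contact at position 295 in the RF1 complex replaced by an
R-RTi-mediated contact in mtRF1.

## Mitochondrial terminability

`classify_termination()` applies, in fixed order: (1) in-frame terminal
UAA/UAG → `standard`; (2) terminal AGA/AGG with U immediately 5' →
`frameshift_terminable` (the −1-shifted codon is UAG in both cases;
only the −1 shift is evaluated); (3) with polyadenylation completion
enabled, coding length ≡ 1 or 2 (mod 3) with annotated terminus U/UA →
`polyA_completed` (completed to UAA); (4) otherwise `not_terminable`.
UGA is never a stop under the vertebrate mitochondrial code. Rules 1–2
read the terminal triplet only for in-frame (length ≡ 0 mod 3) coding
sequences; out-of-frame termini are exactly the incomplete-stop cases
of rule 3.

Polyadenylation completion defaults **on**: vertebrate mitochondrial
mRNAs with incomplete U/UA stops are completed to UAA during
maturation, and genome-level "all terminable" statements presuppose it.
The flag makes the strict annotated-terminus reading available too.

Sequences are stored as DNA (T) and reported as RNA (U); GenBank
coordinates are 1-based inclusive with `join`/`complement` and
origin-spanning segments on circular genomes supported; pseudogenes are
excluded. `scan_genome()` ANDs per-gene terminability into the genome
verdict.

## Synthetic data: what it emulates, what it does not

The generators exist so that every detector can be tested against
*planted* truth recorded in a manifest, not truth re-derived by the
code under test.

* `gen_alignment()` plants exactly `k` discriminating columns; all
  other columns are either fully conserved across both families or
  carry a within-family substitution that breaks perfect conservation,
  so planted truth and criterion-satisfying truth coincide exactly.
  Insertion blocks are clean (all members of the carrier present).
* `gen_structure()` places planted hydrogen-bond and clash pairs at
  exact distances on a well-separated grid, optionally adds a
  decoding-center state and a release-factor fixture, and applies one
  seeded rigid transform to the whole model (which preserves all
  internal geometry and exercises pose invariance).
* `gen_mitogenome()` lays out genes with exact termini and preceding
  bases, minus-strand genes reverse-complemented, optional
  origin-spanning rotation.

Study-scale defaults were fixed once to mirror the study conditions:
17 sequences per subfamily over a 360-residue reference; 24 planted
discriminating positions — the five named substitutions (Glu-119→Ile,
Thr-186→Val, Ser-195→Gly, Arg-298→Gln, Lys-301→Arg) plus nineteen more
distributed 20/2/1/1 over domain 2, switch loop, domain 1, domain 3 —
with the RT insert (length 2) anchored at 115 and the GLS insert
(length 3) directly after the PXT motif; background conservation 0.5.
The human-like mitogenome has 13 CDS: 8 standard stops, 3 incomplete
(U/UA), and U-preceded AGA/AGG on CO1 (plus strand) and ND6 (minus
strand).

What the synthetic data does **not** emulate — and hence what passing
tests do and do not show about real data: columns are independent (no
phylogenetic correlation, so real alignments with rate variation or
misalignment may behave differently near the strictness boundary);
within-family conservation outside planted columns is binary, making
cross-family identities higher than the ~39–45% of the real proteins;
coordinates are idealized rigid templates with no chemical plausibility
beyond the planted constraints; mitogenome spacers are uniform random
DNA with none of the tRNA punctuation of real mitogenomes. Tests on
these fixtures establish the *correctness of the computations*, not the
biological values themselves; the published-number checks run on
fetched real inputs (see `scripts/fetch_data.R`) where available.

## Numerical choices and degenerate inputs

Determinism everywhere: one Mersenne-Twister seed per recipe, recorded
in the manifest, with the session RNG state restored afterwards;
identical recipe and seed give byte-identical files. Generated
coordinates are rounded to the PDB's 0.001 Å precision so in-memory and
reparsed models agree to that tolerance. Detector outputs are
deterministically ordered (columns ascending; bonds by donor/acceptor
id; clashes by atom ids). Ties: altloc resolution prefers A; consensus
residues break alphabetically; state classification prefers stacked <
unstacked < recognized. Degenerate inputs fail with classed conditions
(`format_error`, `label_error`, `cardinality_error`, `bounds_error`,
`selection_error`, `lookup_error`, `degeneracy_error`,
`resolution_error`, `validation_error`, `stage_error`), which the
test-suite asserts by class rather than message.

Problem sizes used by the test suite — chosen as comfortably
desk-scale while exercising every code path: 200 random alignments for
the detector/oracle equivalence sweep, ≤ 500-atom models for the
all-pairs geometry oracles, 1000 permutations for the planted-cluster
significance check, and the study-scale fixtures above for the
end-to-end pipeline.

## The pipeline

`validate_config()` parses a YAML configuration and collects *all*
problems before failing; `run_pipeline()` executes the configured
stages (any subset: sequence-only, structure-only, genomes-only runs
are supported), stamps every output with the configuration checksum and
seed, writes TSV/JSON per stage plus a consolidated `report.json`, and
is rerun-identical for identical configurations. Progress goes to the
message stream, never into outputs. Each stage failure is reported with
the stage's name.

## Known limitations

* The discrimination criterion is intentionally strict; near-perfect
  conservation (one deviant sequence) yields nothing, which matches the
  published criterion but is brittle for noisy alignments.
* Hydrogen-bond detection without hydrogens is purely geometric;
  acceptor–acceptor near-contacts are never reported as bonds, but
  donor geometry (hybridisation, secondary-structure context) is not
  evaluated.
* Domain boundaries outside the switch loop are editorial; divergence
  counts in the boundary zones depend on them and they should be set
  from a structure when one is available.
* mmCIF is not parsed; inputs must be fixed-column PDB.
* The binding-compatibility verdict considers only the decoding
  nucleotides, not the mRNA, tRNA or the remainder of the 30S subunit.
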