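---
title: "Methods: composition, rRNA contacts, CEF and independent contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition, rRNA contacts, CEF and independent contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocef)
library(dplyr)
```

## The problem

Small-subunit ribosomal proteins (S2–S21) assemble onto 16S rRNA, a
polyanion, and are famously rich in lysine and arginine. Two questions
drive this package. First, are those positive residues concentrated at
the protein–rRNA interface, beyond what their overall abundance
predicts? Second, do thermophilic bacteria (optimal growth above 50 °C)
and mesophilic bacteria differ in r-protein composition, and do any such
differences reach into the interface itself? Both questions are
comparative: species share ancestry, so naive cross-species tests
overstate the evidence, and the second question in particular needs a
phylogenetic method.

S1 is deliberately excluded everywhere: it is an atypical, loosely
associated protein and not part of the S2–S21 analysis set; the reader
functions refuse it.

## Composition, categories and net charge

`aa_composition()` counts the 20 standard residues over the ungapped
part of each aligned sequence. Gaps (`-`, `.`) and ambiguity codes
(B, Z, X, U) are excluded from numerator and denominator alike, so
proportions always sum to 1 and are invariant to gap insertion; ambiguity
exclusions are reported via a message. An all-gap sequence is an error
rather than a silent `NaN`.

Net charge is the integer `(#K + #R) − (#D + #E)`: at physiological pH
lysine and arginine carry +1, aspartate and glutamate −1, everything
else is treated as neutral (histidine included — its side chain is
mostly unprotonated at pH 7).

The five chemical categories default to positive = {R, K},
negative = {D, E}, aromatic = {F, W, Y}, polar = {S, T, N, Q, C, H},
nonpolar = {G, A, V, L, I, P, M}. Only the positive, negative and
aromatic memberships are uncontroversial; histidine's placement is a
documented choice, and `default_category_map()` returns a plain list so
users can reassign it. `check_category_map()` enforces that the
categories partition the alphabet, which is what makes the five
category fractions sum to 1.

Temperature handling mirrors the common four-way field classification
— cryophile (< 10 °C), lower mesophile ([10, 35)), upper mesophile
([35, 50]) and thermophile (> 50) — collapsed to a binary
mesophile/thermophile split at 50 °C because the three cooler classes
behave alike in composition. A species at exactly 50 °C is a mesophile:
the thermophile class is strictly "above 50".

The binding-order table (primary binders S4, S7, S8, S15, S17, S20 —
exactly six — secondary and tertiary for the rest) follows the classical
30S assembly map and is overridable from TSV, since different
reconstructions of the map move one or two proteins between the
secondary and tertiary tiers.

## Contact detection

A residue contacts the rRNA when any of its atoms lies within 3.5 Å of
any rRNA atom. Numerical choices, each of which can move individual
contacts:

* the cutoff comparison is **inclusive** (≤ 3.5 Å);
* hydrogens are dropped when present — the reference crystal structures
  lack them, and keeping them in other depositions would make results
  deposition-dependent;
* waters, ions and all other HETATM records are excluded on both sides;
* where alternate locations exist, only the highest-occupancy conformer
  of each atom is kept (ties break on altloc letter).

The default search builds a cell list: cubic cells with edge equal to
the cutoff, so each protein atom scans at most 27 cells of RNA atoms.
This is the only compiled code in the package. Its contract is exact
equivalence with the quadratic all-pairs scan, which remains available
as `method = "brute"` and is held against the grid on randomized
structures in the test suite — if the two ever disagree, the grid is
wrong by definition.

Residue *positions* are 1-based indices into the ungapped chain
sequence, and alignment columns are 1-based as well, matching the
conventions of ape, Biostrings and bio3d.

## Cross-species projection

Contacts are only observed in two crystal structures (E. coli 2AVY and
T. thermophilus 1J5E; chain maps for both ship with the package). To
carry them to every aligned species, contact positions of each
reference are mapped to alignment columns, and a column is kept only
when **both** references have a non-gap residue there and both residues
are contacts. This intersection is deliberately conservative: it
undercounts each species' true interface but avoids imputing contacts
that are specific to one lineage. Projection onto a species takes its
non-gap residues at the shared columns; gapped columns contribute
nothing, so a species' contact count never exceeds the number of shared
columns.

## The Contact Enrichment Factor

For each residue type, `CEF = (Rc/C) / (Rt/L)`. Cells with `Rt = 0` or
`C = 0` are *undefined* — flagged, excluded from downstream tests, never
imputed as 0 or 1 (a residue that does not occur in a protein carries no
information about interface preference).

Species-level aggregation **pools counts** — Σ`Rc`, Σ`C`, Σ`Rt`, Σ`L`
over the species' proteins, then one ratio — rather than averaging
per-protein CEFs. CEF is a ratio of proportions; the mean of ratios
weights a 50-residue protein as heavily as a 250-residue one and is not
the CEF of any observable object, whereas pooled counts equal the CEF of
the concatenated proteome (a test asserts exactly this equivalence).
`aggregate_cef(mode = "average")` provides the ratio-averaging variant
for comparison.

Two identities pin the implementation down: when the contact composition
equals the overall composition, every defined CEF is exactly 1; and
Σ over residues of `cef × (Rt/L)` is exactly 1 whenever all cells are
defined. Both are asserted to near machine precision.

## Statistical layer

All tests return one uniform tibble row. Choices that matter:

* **Two-sample t** is the pooled-variance Student form (`welch = TRUE`
  opts into unequal variances).
* **Spearman** computes ρ as the Pearson correlation of mid-ranks and
  takes p from the t-approximation `t = ρ√((n−2)/(1−ρ²))` on n − 2 df.
  Exact permutation p-values are impractical at hundreds of species and
  unnecessary at these sample sizes.
* **Sign test**: exact two-tailed binomial at p = ½,
  `p = min(1, 2·P(X ≥ max(k, n−k)))`. Exact zeros are ties, carry no
  direction, and are dropped; an all-tie sample returns p = 1.
* **Fisher's exact test** reports `sqrt(χ²/N)` (from the
  continuity-uncorrected Pearson χ² of the same table) as its effect
  size under the neutral name `effect_size` — this is the φ-style
  association measure.
* Degenerate inputs (zero-variance samples, zero-margin tables) return
  flagged rows instead of crashing, so mapped tests over many residues
  never abort a whole report.
* p-values are reported raw. The per-residue screens are run at
  α = 0.01 without multiplicity correction; with 20 residues this is a
  deliberate, transparent choice (≈ 0.2 expected false positives per
  screen), and callers who want Holm or BH can apply `p.adjust` to the
  returned column.

## Independent contrasts with a binary trait

`pic_contrasts()` runs one Felsenstein pruning pass in which the binary
temperature trait travels as a 0/1 continuous character alongside the
variable of interest. At each internal node the two daughter values of
both characters are combined into branch-length-weighted ancestral
values, daughter branch lengths are adjusted upward by the pruning
recursion, and the node yields a contrast of the variable **iff** its
two daughter values of the binary trait differ by more than 1e-9.
Contrasts are standardized by the square root of the summed adjusted
daughter branch lengths and oriented thermophile-minus-mesophile, so a
positive mean contrast reads directly as "elevated in thermophiles".

Design decisions in this module:

* The trait-divergence rule is this package's own selection criterion.
  Established comparative toolkits select contrast nodes for binary
  traits by related but differently specified sister-taxa/paraphyletic
  rules; the variant here preserves the two properties that matter for
  the tests — independence (each node used once) and direction — and
  labels each contrast `sister_taxa` (both daughters tips) or
  `paraphyletic` for inspection. Identity with any particular external
  tool's node set is not guaranteed.
* Polytomies are resolved deterministically (`ape::multi2di`,
  `random = FALSE`) into zero-length binary branches before the pass.
* Branch lengths below `min_branch` (default 1e-8, in the tree's own
  length units) are floored there so every contrast variance is
  positive. The floor is far below any real substitutions/site branch
  length and only matters for degenerate inputs like resolved
  polytomies.
* A uniform binary trait yields an empty contrast set, not an error —
  pipelines over many variables should glide over uninformative ones.
* Inference: one-sample t against 0 with df = N − 1, plus the exact
  sign test on contrast directions; the significance flag in pipeline
  reports means "at least one of the two rejects at α".

The standardized-contrast machinery is cross-checked in the tests
against the classical contrasts implementation in ape on fixtures where
every node diverges, and against hand-executed pruning on a four-tip
tree.

## The synthetic world

The generators produce data with the statistical structure the analysis
assumes, and nothing more:

* **Trees**: Yule pure-birth (`ape::rphylo`, death 0), default 64 tips,
  birth rate 1. Sixty-four species keeps every simulation affordable
  while giving trees deep enough for trait clustering.
* **Temperature trait**: symmetric two-state Markov chain down the tree,
  root mesophile, default switch rate 0.3 per unit branch length. This
  produces phylogenetically clustered thermophily (typically 10–25
  trait-divergent nodes on a 64-tip tree) rather than independent coin
  flips at the tips, which is the regime that makes PIC necessary.
* **Proteomes**: residues i.i.d. from a baseline frequency vector
  shaped like real r-proteins (K ≈ 11%, R ≈ 10%, acidic and aromatic
  residues scarce), with an additive shift (default +0.02 on R, I, Y and
  −0.03 on S, T, renormalized) for thermophiles. Sequences are emitted
  pre-aligned and gap-free because alignment is upstream of this
  analysis; `gap_rate` punches random gaps purely to exercise gap
  handling. There is **no positional conservation** by default — each
  species' sequence is an independent draw.
* **Conserved interfaces**: because of that independence, contact
  columns of one species say nothing about another's residues, and the
  shared-column projection would (correctly) find no cross-species
  enrichment. `simulate_interface_columns()` therefore plants a single
  per-protein interface column set shared by all species, at which
  `simulate_proteomes()` multiplies K/R odds by the configured bias —
  emulating an interface that evolution keeps positively charged, the
  premise the projection logic relies on.
* **Complexes**: one pseudo-atom per residue on a 6 Å-spaced line;
  planted contact residues get an RNA pseudo-atom 3.0 Å away, all other
  residues sit ≥ 5 Å from every RNA atom, plus a distant decoy RNA
  backbone. The contact detector is geometry-agnostic, so this minimal
  geometry exercises it completely (boundary behaviour is tested
  separately at 3.50 vs 3.51 Å) while keeping files a few kilobytes.

Every generator is a pure function of (configuration, seed).

What passing synthetic tests does *not* show: real alignments have
indels, covarying sites and alignment error; real interfaces have
side-chain geometry, water-mediated contacts and modified nucleotides;
real growth-temperature labels are noisy. Results on real data inherit
those caveats.

## Calibration and known limitations

* Under a Brownian null on 64-tip trees, standardized contrasts at
  trait-divergent nodes are ≈ N(0, 1) (the acceptance suite measures
  mean and variance over 1000 replicates) and the PIC t-test holds its
  nominal 5% size.
* The exact sign test is conservative by construction: its attainable
  size at N contrasts is the largest achievable two-tailed binomial
  level below α, about 0.036 at N = 28 and smaller for smaller N, so
  its measured type-I error sits near 0.03 rather than 0.05. This is a
  property of exact discrete tests, not a defect; the t-test carries
  the nominal-level role.
* Simulation sizes used by the tests and the acceptance script — 1000
  replicates for calibrations, 200 for recovery rates, 100 structures
  for oracle equivalence — were chosen to keep Monte-Carlo error well
  inside the tolerance bands while the full run stays in the minutes
  range on one CPU.
* The reference chain maps for 2AVY and 1J5E are taken from the PDB
  annotations; the interface-electrostatics check against those two
  structures requires downloading them and is the only part of the
  suite that needs a network.
* mmCIF input, solvent accessibility, interface area and base-stacking
  geometry are out of scope; the contact definition is purely
  distance-based.
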