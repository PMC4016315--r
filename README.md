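# ribocef

Comparative analysis of the amino-acid composition of bacterial 30S
ribosomal proteins (r-proteins S2–S21) and of their electrostatic
interface with 16S rRNA. The package is aimed at structural
bioinformaticians and molecular evolution researchers who want to ask:
are positively charged residues concentrated where r-proteins touch the
rRNA, and do thermophiles and mesophiles differ in composition once
shared ancestry is accounted for?

## What it computes

**Composition and net charge.** From per-protein amino-acid alignments
(FASTA), per-sequence residue proportions, chemical-category fractions
(positive, negative, polar, nonpolar, aromatic) and the net charge

    net charge = (#K + #R) − (#D + #E)

with gaps and ambiguity codes excluded throughout. Species are split
into mesophiles (optimal growth ≤ 50 °C) and thermophiles (> 50 °C).

**rRNA contact sites.** In a 30S crystal structure, a protein residue is
a *contact residue* when any of its atoms lies within 3.5 Å (inclusive,
all-atom) of any 16S rRNA atom. Contacts detected in the two reference
structures (*E. coli* 2AVY, *T. thermophilus* 1J5E) are intersected on
the alignment — a column counts only if **both** references contact there
— and these conservative shared columns are projected onto every other
species through the alignment.

**Contact Enrichment Factor.** For each residue type,

    CEF = (Rc / C) / (Rt / L)

where `Rc` is the number of contact residues of that type, `C` the total
contact count, `Rt` the number of residues of that type in the protein
and `L` the protein length. CEF > 1 means the residue is
over-represented at the rRNA interface relative to its overall
abundance; CEF = 1 means indifference. Species-level CEF pools counts
across proteins (equivalent to one concatenated pseudo-protein).

**Phylogenetically independent contrasts.** Thermophily is clustered on
the tree, so species are not independent observations. A Felsenstein
pruning pass treats the binary temperature trait as a 0/1 character;
every node whose two daughter values of the trait differ contributes one
standardized contrast of the continuous variable (composition, CEF, net
charge), oriented thermophile-minus-mesophile. Inference uses a
one-sample t-test of the contrasts against mean 0 (df = N − 1) and an
exact binomial sign test on the contrast directions.

A synthetic-data generator (`simulate_*`) produces Yule trees, Markov
temperature traits, trait-shifted proteomes and toy protein–RNA
complexes with known planted contacts, so the whole pipeline is testable
offline.

## Worked example

Simulate 64 species with a planted thermophile shift (+0.03 on arginine,
balanced by −0.015 on serine and threonine) and test every residue with
independent contrasts:

```r
library(ribocef)
library(dplyr)

cfg   <- sim_config(n_species = 64,
                    thermo_effect = c(R = 0.03, S = -0.015, T = -0.015))
study <- simulate_study(cfg, seed = 42)
table(study$traits$binary_class)
#>   mesophile thermophile
#>          46          18

report <- run_thermo_pic(study$seqs, study$tree, study$traits, alpha = 0.01)
report %>% filter(level == "residue", variable %in% c("R", "S", "T", "K"))
#> # A tibble: 4 × 9
#>   level   variable     N mean_contrast t_statistic       t_p n_positive    sign_p significant
#> 1 residue K           28      0.000217       0.253 0.803             17 0.345     FALSE
#> 2 residue R           28      0.0117         4.42  0.000146          23 0.000912  TRUE
#> 3 residue S           28     -0.00638       -4.85  0.0000458          3 0.0000274 TRUE
#> 4 residue T           28     -0.00594       -3.92  0.000553           4 0.000180  TRUE
```

The 28 trait-divergent nodes yield a significantly positive mean
contrast for R (elevated in thermophiles) and negative ones for S and T
(depleted), exactly the planted effect; K, which was not shifted, stays
non-significant. The same report carries the five chemical categories
and net charge (the planted shift also surfaces as `positive` up,
`polar` down, net charge up).

Contact detection and CEF on a toy complex:

```r
cx  <- simulate_complex(study$seqs$aligned_seq[1], cfg, seed = 1)
det <- contact_residues(cx$atoms, "A", "B")          # 3.5 Å rule
identical(det$position, which(cx$truth$contact))     # TRUE: planted truth recovered
```

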