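---
title: "Methods: simulating and analysing a dual-genome ddRAD survey"
author: "symrad developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a dual-genome ddRAD survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`symrad` re-implements, as a tested and fully synthetic-data-driven
pipeline, a population-genomic analysis design in which a single ddRAD-Seq
library per fish light organ captures two genomes at once: the diploid host
(a coral-reef cardinalfish) and the population of luminous bacterial
symbionts living in its light organ. The analytical payoff of that design
is a *contrast*: the host is effectively panmictic across reefs while the
symbiont shows genetic structure at scales of tens of kilometres, which is
evidence that host behaviour (site fidelity, local symbiont shedding)
structures the symbiont population even in an open ocean. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic data can and cannot establish.

## The simulation world

### References and digest

`make_reference()` draws i.i.d. uniform nucleotide scaffolds (default 8 ×
25 kb = 200 kb, standing in for a ~4.5 Mb bacterial assembly at desk
scale) and tiles non-overlapping CDS features on alternating strands to a
target coding fraction (default 0.6, typical for a bacterial genome). CDS
intervals are annotation-only: their sequence content is uniform DNA, not
ORF-validated, which is irrelevant to the codon-local variant classifier
but means whole-ORF translation of a toy gene is meaningless.

`digest_and_select()` performs the in-silico double digest with exact
forward-strand site matching (EcoRI `G^AATTC`, MseI `T^TAA`, both
configurable), keeps fragments with one end of each type inside the
size-selection window (default 150–450 bp), and records which end is the
EcoRI end. At these defaults a 200 kb genome yields ~30 retained
fragments — the same marker density per megabase as the ~600 loci the real
study recovered from 4.5 Mb, so desk-scale locus counts are about 20×
smaller than the study's.

### Symbiont strain pools

`simulate_strain_pools()` plants substitution variants against the
reference in a two-level hierarchy: island *groups* carry shared variants
at per-site density `theta_b` (default 0.002), and each *strain*
additionally carries private variants at density `theta_w` (default
0.003). One pool of `strains_per_pool` (default 12) strains exists per
sampling site; sites inherit island-group labels from the design. Position
collisions are resolved by keeping the first planted variant (logged).
Every variant's coding consequence is pre-computed into the truth table
with the same classifier used downstream.

Two considerations fix `theta_w = 0.003`, chosen once: (i) conspecific
bacterial strains within a local population typically differ by ~0.1–0.5%
of sites, and 0.003 puts roughly one segregating variant per strain per
90 bp locus — matching the single-variant outlier haplotypes that dominate
the real study's outlier table; (ii) the read partitioner is contractually
capped at 4 mismatches per 90 bp, so substantially higher divergence
creates strain×locus combinations that systematically drop out
(reference bias), contradicting the stated ≥98% partition-accuracy
property of the simulation world. Note that even at 0.003 a small amount
of divergent-allele dropout remains — as it does in any reference-aligned
RAD analysis.

### Light organs, host, reads

`compose_light_organ()` draws the strain number k uniformly from 2–10
(the empirically observed range; its mean of 6 matches the reported mean
of six strains per organ) and assigns relative abundances from a
symmetric Dirichlet(1). The census size and true abundance law inside a
light organ are unobserved; Dirichlet(1) is a deliberately uninformative
stand-in and is flagged as unvalidated.

`simulate_host()` draws a panmictic diploid host by default
(`fst_target = 0`); for power analyses a Balding–Nichols beta perturbation
of per-population allele frequencies realises a target Weir–Cockerham
F_ST (recovered to ±0.02 for targets 0–0.2 in tests). Host reads come from
an independent toy host reference digested the same way, with one biallelic
SNP planted per locus template; each individual contributes its two allele
haplotypes at coverage proportional to dosage.

`generate_reads()` emits 100 bp single-end reads: a 10 bp inline barcode
(all barcodes mutually ≥3 mismatches apart) followed by the 90 bp template
taken from the EcoRI end of the fragment, reverse-complemented when the
EcoRI end is the right end. Depth per (fragment, haplotype) is negative
binomial with mean `lambda * abundance` and dispersion `size = 5`
(over-dispersion chosen to exercise the depth filters; the real coverage
law is unknown). Substitution errors are uniform at `error_rate` (default
0; 0.001 in accuracy tests), qualities are constant Q37, and every read
carries a truth tag (origin, sample, haplotype, fragment, truncation flag)
in the FASTQ comment, where standard parsers ignore it.

## The processing pipeline

*Demultiplexing* assigns reads to the unique nearest barcode within one
mismatch (rescue configurable to exact-only). *Quality filtering* is a
sliding-window mean-quality rule (window 15% of read length, threshold
Q20): the source protocol's "Phred score of 33" is read as the Phred+33
*encoding*, since a literal Q33-everywhere filter would be an unusual and
much harsher rule; that literal behaviour remains available via
`rule = "min_q"`.

*Alignment* is a deliberately simple seed-and-extend ungapped matcher
(the simulator plants no indels): three tiled exact seeds of 20 bp
(start/middle/end, both strands) generate candidate placements, which are
extended by Hamming distance with a 4-mismatch cap. The uniqueness score
is a monotone MAPQ surrogate — 60 for a unique best placement two or more
mismatches clear of the runner-up, 3 for a tie, linear between — and the
only contract that matters downstream is the >20 cut. Two end seeds are
not enough: a haplotype with variants near both read ends would be
invisible, which is why a middle seed exists.

*Partitioning* sends confident symbiont alignments (uniqueness > 20) to
the symbiont bin, screens the remainder against optional decoy genomes
(contaminant bin), and classifies everything else as host. Reads that
aligned to the symbiont but failed the uniqueness cut fall through the
same decoy/host route by default (`ambiguous_to = "unassigned"` drops
them instead); their count is logged as low-uniqueness leakage. Per-sample
QC discards libraries under 100,000 reads or 100× mean stack depth at
survey scale; a `scale` multiplier adapts both thresholds to desk-scale
simulations.

*Locus calling* groups symbiont reads into reference-anchored loci by
(scaffold, leftmost position, strand); within a sample, identical reads
form stacks, stacks below depth 3 are dropped, and survivors are the
sample's haplotypes. Host reads are assembled de novo: per-sample stacks
(depth ≥ 3) merge greedily deepest-first within 2 mismatches; sample
consensus sequences merge across samples within 1 mismatch,
deepest-first with lexicographic tie-break. Host genotypes take the
leftmost polymorphic column per locus (0/1/2 minor-allele dosage; >2
haplotypes ⇒ missing), keep loci called in ≥70% of every population with
MAF ≥ 5%.

*The filter cascade* reproduces the published missing-data policy: loci
observed in ≥70% of all organs, then in ≥50% of every location×year
population; datasets are split (each multi-site year, plus every location
sampled ≥3 years); within each dataset individuals then loci with >15%
missingness are removed, in that order, one pass (an iterate-to-fixpoint
mode exists behind `iterate = TRUE`). Missingness is defined at locus
level: a sample with no surviving haplotype at a locus is missing at all
of that locus's columns, never "absent".

## Statistics

All inferential machinery is implemented from first principles and each
piece is tested against an independent oracle (closed form, brute-force
set arithmetic, exhaustive permutation enumeration, the Gower-trace
PERMANOVA formulation, scalar Weir–Cockerham 1984 formulas) and — where
one exists — against the corresponding vegan function.

- **Bray–Curtis** on presence/absence, pairwise-complete columns by
  default (`mode = "complete"` restricts to fully observed columns); a
  pair with no jointly observed presence gets d = 1 and is logged.
- **Euclidean genotype distance** with pairwise-complete columns rescaled
  by √(L/L_obs).
- **PCoA** by Gower double-centering; coordinates only for positive
  eigenvalues; negative eigenvalues are reported, not corrected (no
  Lingoes/Cailliez, matching the cited analysis's default); axis signs are
  fixed deterministically.
- **PERMANOVA** partitions Σd²/n with free label permutation and the
  (1+count)/(1+N) p-value estimator (never zero); `exact = TRUE`
  enumerates all n! labelings for n ≤ 8. Defaults: 999 permutations
  (adonis convention); Mantel and F_ST use 1,000 (the protocol's stated
  number). Pairwise PERMANOVA applies Bonferroni by default — the only
  correction the source protocol names — with Holm/BH exposed.
- **Weir–Cockerham F_ST**: per-locus variance components a/b/c, θ =
  Σa/Σ(a+b+c) over loci with defined denominators; permutation of
  individuals across each pair; Bonferroni across pairs.
- **Strain count**: per organ, the maximum over loci of the number of
  present haplotypes — a lower bound on the true strain number (haplotypes
  cannot be concatenated across loci). It equals k exactly when some locus
  distinguishes all k strains.
- **CAP (db-RDA)**: PCoA coordinates regressed on the centered factor
  indicator matrix; constrained axes from the SVD of the fitted values;
  sample scores are projections of the full coordinates (weighted-average
  "wa" scores, matching `capscale`'s display); haplotype scores are
  presence-weighted means of sample scores. Outlier selection takes the
  >99%/<1% percentile tails per axis (per-axis, as in the study's score
  panels) and keeps candidates whose |score| exceeds `gap_factor` (default
  2) times the cut magnitude — an explicit operationalisation of the
  study's informal "large differences" rule; the gap rule is an
  interpretation, and raising `gap_factor` never adds outliers.
- **Variant annotation** translates the affected codon strand-aware
  (frame anchored at the feature start on +, at the end on −; standard
  genetic code) and maps synonymous→LOW, non-synonymous→MODERATE,
  stop-gained→HIGH, upstream (≤500 bp before a CDS start, strand-aware)
  →MODIFIER; reference-identical haplotypes are "consensus" with no
  effect. Stop-loss is not modelled separately (collapses into
  non-synonymous); variants outside CDS and upstream windows are
  "intergenic"/none. The 500 bp window is a configurable choice — the
  source table reports "Upstream" without a distance.

## Calibration, and what a green test establishes

The type-I calibration of PERMANOVA deserves a note. With site-private
strain pools, site labels are **not exchangeable even when θ_b = 0**:
samples from one site share that site's realised strains, and PERMANOVA
correctly rejects far above the nominal rate. That is not an artifact —
it *is* the local-enrichment effect the study proposes, moved into the
null. The calibration test therefore uses the exchangeable null the
specification intends ("labels exchangeable"): every light organ draws
from one shared environmental pool. Under that null the measured
rejection rate at α = 0.05 is ≈ 0.05 over 500 replicates; under the
structured world (θ_b = 0.002, 4 sites × 20 organs) p < 0.001 in ≥ 90% of
replicates; and the end-to-end read-level pipeline reproduces the
host/symbiont contrast (host p > 0.05, symbiont p < 0.01) in ≥ 80% of
replicates at a scaled size (32 organs, 60 kb genome) chosen to fit the
test budget.

Incidentally, this calibration caught a real defect during development: an
order-insensitive per-sample seed hash gave identical strain compositions
to samples whose identifiers were anagrams, inflating the type-I rate
several-fold before the fix.

What the generator does *not* emulate: indels, PCR duplicates, adapter
read-through, GC and fragment-length bias, quality degradation along the
read, chimeras, or contamination beyond explicit decoy genomes; the light
organ census size and abundance law are invented (Dirichlet(1)); the toy
genomes are uniform DNA without repeat structure (so multi-mapping is
rarer than in real genomes); and desk-scale locus counts (~30) are ~20×
below the study's 601, which matters most for the strain-count estimator —
with fewer loci there is less chance that *some* locus witnesses all k
strains, so the estimator's mean sits somewhat below the true mean k even
though every per-organ estimate remains a correct lower bound (the suite
checks the bound and its tightness condition, and that mean k itself is
6 ± 1 over 282 organs). A green suite therefore establishes the
implementation's correctness contracts and the qualitative
host–symbiont contrast, not the study's exact headline numbers, which
derive from an unavailable sequencing accession.

## Numerical and degenerate-input choices

Permutation p-values use (1 + #{stat ≥ obs}) / (1 + N) with a 1e-12 slack
on the ≥ comparison; exact modes count the identity permutation, so p > 0
always. Eigenvalues within 1e-9 of zero (relative) are treated as null in
PCoA/CAP. Ties in the de novo merges are broken deepest-first then
lexicographically, making catalogs deterministic. Degenerate inputs error
loudly and early: singleton PERMANOVA groups, one-level CAP constraints,
constant Mantel vectors or regression predictors, empty references,
sample pairs sharing zero loci, a filter stage that empties a population,
and all-sample QC failure each halt with a named message rather than
propagating NaN. Fragments shorter than the 90 bp template yield
truncated, truth-flagged reads which the catalog builder excludes by
modal-length filtering (logged).
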