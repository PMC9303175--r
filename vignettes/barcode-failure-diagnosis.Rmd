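---
title: "Diagnosing rDNA barcode failure: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing rDNA barcode failure: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnadiv)
```

## The problem

DNA barcoding assumes that sequence variation within a species is smaller
than the variation between species; the margin between the largest
intraspecific distance and the smallest interspecific distance is the
*barcode gap*. In yeasts the primary barcodes are the ITS segments and the
LSU D1/D2 domain of the rDNA, which is a multicopy gene family. Concerted
evolution (gene conversion across tandem repeat arrays) normally keeps the
copies of one genome nearly identical, so a single Sanger read represents
the strain. In the *Metschnikowia pulcherrima* clade this assumption
collapses: rDNA units are dispersed over chimeric, admixed genomes, cannot
be homogenized, and accumulate deep intragenomic heterogeneity — to the
point where diversity *within* one genome rivals or exceeds the diversity
*between* type strains, and the barcode gap disappears.

`rdnadiv` implements the full diagnostic pipeline for this failure mode:

1. **distance** — uncorrected pairwise distances with explicit ambiguity
   policies, intragenomic/interstrain partitions, and the barcode-gap
   report;
2. **structure_sites** — variable-column detection and classification
   against an rRNA secondary structure (wobble pairing, compensatory base
   changes, mismatches, pseudogene flags);
3. **phylonet** — neighbour joining, neighbour-net circular split systems
   with non-negative least-squares weights, and quartet treelikeness
   statistics (delta score, Q-residual);
4. **repeat_scan** — seed-and-extend mining of barcode units and gene
   copies in assemblies, complete/truncate classification, haplotype
   grouping;
5. **consensus** — polymorphic IUPAC consensus barcodes and an in-silico
   Sanger consensus with a minor-variant detection threshold;
6. **simulate** — a forward simulator of repeat evolution that generates
   every input above with ground-truth labels.

The numbered scripts under `analysis/` run these stages as a narrative
workflow over simulated study conditions and write their tables under
`results/`.

## Distances and the barcode gap

Distances are uncorrected (p-) distances over pairwise-deleted alignments:
positions where either row carries a gap (or `N`, by default) are excluded,
and the distance is `100 * differences / compared_sites`. No
Jukes–Cantor/Kimura correction is applied — the quantities of interest
(difference counts between cloned repeats) are raw substitution counts, and
corrections would only blur the gap arithmetic.

Two ambiguity policies are available. Under `strict`, any two distinct
symbols differ — appropriate for cloned sequences, which carry no ambiguity
codes. Under `set-overlap`, two symbols differ only when their IUPAC
expansions share no base (`A` vs `R` is not a difference) — appropriate as
soon as a consensus or database record with ambiguity codes participates.
The policy used is recorded on every matrix. `strict` distances always
dominate `set-overlap` distances, a property the test suite checks.

The barcode-gap report covers every unordered taxon pair with at least two
members each: `gap = min_inter − max(max_intra_A, max_intra_B)`, with
`gap_present = gap > 0`. Pairs with singleton taxa are reported with
undefined intra maxima and flagged rather than dropped. Distances with zero
comparable sites are errors, never zeros: silently returning 0 for
non-overlapping truncated sequences would fabricate identity.

## Site classification against secondary structure

Secondary structures are *inputs* (dot-bracket strings on a reference
transcript); the package does no folding. A column of the alignment is
**variable** when at least two of `A/C/G/U` occur among ungapped rows and
the total minor-state count reaches `min_minor_count` (default 3). The
default deliberately excludes singletons and doubletons, which in cloned
amplicon sets are dominated by polymerase errors. Dimorphic columns are the
classical SND sites.

At paired positions the per-sequence (row-wise) combination of (site,
partner) states is examined — not the column marginals. This distinction
matters: marginal variability on both strands could be coincidental,
whereas row-wise reading distinguishes a genuine compensatory base change
(all combinations canonical, but different between sequence groups) from a
broken pair. The classes are:

* `neutral_unpaired` — variation at a loop position;
* `wobble_neutral` — one side varies and every observed state still pairs
  canonically (Watson–Crick or G·U wobble) with the invariant partner;
  these single-side canonical-preserving changes are hemi-CBCs and are
  reported as such in the `subtype` column;
* `CBC` — both columns vary and every observed combination is canonical;
* `mismatch` — some sequence carries a non-canonical combination.

A sequence is flagged as a putative **pseudogene** when it carries a
non-canonical combination at a *CBC-designated* pair (a pair classified
`CBC` from the data, or supplied in the structure's `cbc_pairs`
annotation). Mismatches at other stem positions are reported but are not by
themselves pseudogene evidence: the designated compensatory positions are
the ones whose integrity is required for a functional transcript, which is
exactly why a broken designated pair marks an inactive copy. Columns where
the reference row has a gap carry no structural anchor and are reported as
`unanchored`.

## Trees, split networks and treelikeness

`nj_tree()` implements Saitou–Nei neighbour joining with one deliberate
addition: ties in the Q criterion are broken towards the lexicographically
smallest (row, column) pair, making output deterministic across platforms;
negative branch lengths are clamped to zero with a warning and a count in
the `clamped` attribute. On additive matrices the implementation is exact
(distances regenerate to 1e-9 over 100 random 8-taxon trees), and its
topologies agree with an independent implementation (`ape::nj`) in the
cross-checks.

`neighbour_net()` obtains the circular taxon ordering by the Bryant–Moulton
two-stage agglomeration (delegated to `phangorn::neighborNet`, the
established implementation of that step), enumerates all `n(n−1)/2` splits
compatible with the ordering, and estimates their weights in-package by
non-negative least squares (`pracma::lsqnonneg`, active-set). Splits below
`1e-9` are dropped. On additive input the surviving splits are exactly the
tree's splits with weights equal to branch lengths; on a constructed
4-cycle ("box") metric both incompatible splits are recovered with their
planted weights. Exports are NEXUS splits blocks (readable by standard
split-network viewers) and TSV; no graphical planar layout is attempted.

Treelikeness is quantified by the quartet **delta score**: with the three
pairwise-sum values of a quartet ordered `s1 ≥ s2 ≥ s3`, delta is
`(s1 − s2)/(s1 − s3)` (0 when `s1 = s3`). Additive metrics score 0 by the
four-point condition; a fully conflicting quartet scores 1. The Q-residual
(`((s1 − s2)/scale)²` averaged, with `scale` the mean distance) is reported
alongside. One caveat the workflow makes explicit: on pools of
nearly-identical sequences delta is a ratio of tiny numbers and mostly
measures noise, so the clean reticulation readout is a *matched* comparison
— the same configuration with and without a hybridization event — rather
than absolute delta values.

## Repeat mining

`scan_genome()` is a bespoke seed-and-extend local search: shared k-mers
(default k = 12) between query and contig seed candidate loci on both
strands; each locus is scored by local alignment (match +1, mismatch −1,
gap −2, via `Biostrings::pairwiseAlignment`), and near-complete hits
(local query coverage ≥ 0.75) are refined by a global-in-query alignment so
that terminal substitutions stay inside the hit and coordinates span the
full unit. The refinement is accepted only when it does not degrade
identity (within 0.02): forcing the missing half of a genuinely truncated
unit onto background sequence drops identity, and the guard keeps such hits
truncated rather than "rescuing" them. Same-strand hits within 50 bp are
merged keeping the higher-scoring extension, because heavily mutated
repeats fragment naive seeding.

Completeness is a closed-boundary coverage threshold (default 0.90,
recorded in every report): the notion of a "truncate" repeat is inherently
parameterized, so the threshold travels with the numbers. Haplotype
grouping is single-linkage at a difference threshold (default 0, i.e.
groups of identical sequences); distinguishing positions between groups are
counted between group majority consensuses, with ties broken towards the
alphabetically first base and logged. `gene_copy_report()` applies the same
machinery to gene queries and reports the admixture signature: a genome
whose gene copies differ more from each other than from their counterparts
in other genomes carries orthologues of different descent, not in-place
paralogues.

## Consensus barcodes and Sanger emulation

`iupac_consensus()` calls, per column, every state whose proportion among
ungapped residues reaches `min_proportion`, and emits the IUPAC symbol of
that set — producing the di-, tri- and tetramorphic positions of a
"polymorphic" barcode. When no state reaches the threshold the majority
state is called and the column flagged. Columns that are majority-gap are
emitted as `-` to keep the consensus alignable. `sanger_emulation()` is the
same computation under repeat-abundance weighting with the threshold
playing the role of the basecaller's minor-peak detection limit (default
0.25, chosen so a 3:1 repeat-class imbalance is just detectable; always
emitted in the metadata). Its ambiguity count is exactly the number of
columns whose called set has two or more states — the package's in-silico
analogue of a strain's "taxonomic sequence", and the reason such sequences
can fail to match any individual repeat.

## The simulator

`simulate_dataset()` evolves an ancestral array of repeats down a species
tree (default: six strains in three sister pairs, total depth 0.8 time
units) with a Gillespie event queue per branch — exact rates, no
per-generation loops. Events per repeat: substitution proposals at
`mutation_rate` per site per unit with transition bias κ (default 4,
matching the observed predominance of pyrimidine transitions), gene
conversion (`homogenization_rate`), duplication, deletion, and terminal
truncation clipping a uniform 10–60% of the unit. Proposed substitutions
at unpaired positions always fix; in stems acceptance depends on the
outcome — canonical (incl. wobble) 0.8, non-canonical at a designated CBC
pair 0.4, non-canonical elsewhere 0.05. This acceptance asymmetry is what
concentrates observable variation in loops, and the test suite verifies
that the fraction of variable sites falling in unpaired segments exceeds
the structure's unpaired fraction.

Design choices that deserve justification:

* **Homogenization only acts within arrays.** With `placement =
  "dispersed"` (the default, the clade's situation) gene conversion is
  inoperative; with `"arrayed"` any repeat can overwrite any other. For
  concerted evolution to win, the conversion rate must beat the mutation
  input per repeat (`mutation_rate × length` ≈ 9 per unit at defaults);
  the shipped `homogenized` regime uses 100.
* **Hybridization is block-wise retention.** An event merges two coexisting
  lineages at a stated time; the genome is divided into 20 blocks and each
  block retains one parent's material (probability `retention`). Gene
  copies follow their blocks, except that with probability
  `gene_both_retention` both parental copies of a gene survive — the
  segmental-diploidy route to multi-copy secondary barcodes with
  discordant histories. Events between lineages that have not yet diverged
  (or no longer exist) at the stated time are errors.
* **Hybrid repeat recombination.** Transferring whole repeats between
  genomes leaves the repeat genealogy a tree, which a distance-based
  treelikeness statistic cannot distinguish from vertical descent. The
  sequence-level footprint of reticulation arises when repeats recombine
  across the parental pools while the hybrid genome stabilizes; with
  probability `hybrid_repeat_recomb` an offspring repeat is a two-segment
  parental chimera. This is the mechanism behind the elevated delta scores
  under hybridization.
* **Pseudogene truth is mechanistic and recomputed at emission**: a repeat
  is `truncate` if clipped, `pseudogene` if its final sequence carries a
  non-canonical state at a designated CBC pair. Recomputing from the final
  sequence (rather than trusting event-time marks) means a later reverting
  substitution cannot leave a stale label, and makes the simulated truth
  exactly the quantity the detector estimates. A configurable number of
  pseudogenes (`pseudogene_plants`, default 2 per genome) is additionally
  planted at the tips so that validation always has positives.
* **Cloning samples full-length repeats.** Clones emulate PCR amplicons;
  a repeat missing a primer-flanked end cannot amplify, so truncated
  repeats appear in assemblies but not among clones. (This also prevents
  undefined distances between clones with disjoint truncations.)
* **Calibration.** Defaults (`mutation_rate` 0.03, `birth_rate` 0.5,
  `death_rate` 0.45, `truncation_rate` 0.25, ~12 repeats, 12 clones per
  strain) were chosen once so that the emergent scales are realistic for
  the system being modelled — maximum intragenomic clone distances around
  8–10%, repeat counts per genome in the single-digit-to-dozens range, an
  appreciable truncate fraction, and Sanger-style consensus reads with a
  handful of ambiguous positions. They reproduce qualitative regimes, not
  inferred rates; nothing about them is an estimate of real turnover
  parameters.

Everything is reproducible byte-for-byte from `(config, seed)`; clone
sampling seeds derive from the dataset seed per strain.

### What the simulator does not emulate

Real chromatogram artefacts (quality decay, primer effects), indel
mutations other than terminal truncation, within-species coalescent
structure, selection differentials among repeats, and alignment error
(simulated sequences are born aligned in reference coordinates; a
real-data pipeline would first run a multiple aligner). Passing tests on simulated
data therefore validate the *inference machinery* — that gaps, site
classes, networks, mined repeats and consensus calls are computed correctly
against known truth — not that real Sanger chemistry or real alignment
noise behave this way.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally and 1-based inclusive in all
  human-readable output (TSV, BED-like hit tables).
* `U` and `T` are unified as `T` internally; pairing logic converts to the
  RNA view on the fly, and classification is invariant under the
  representation.
* NNLS uses the active-set `lsqnonneg` with its default tolerance; split
  report threshold 1e-9; duplicate candidate splits are rejected rather
  than silently collapsed.
* Majority-consensus ties resolve towards the fixed base order A < C < G <
  T and are logged; haplotype consensus ties likewise.
* Empty alignments, unmapped taxon labels, non-positive bin widths,
  abundance vectors that do not sum to one, and queries shorter than the
  seed length are typed errors.

## Problem sizes

The shipped workflow and tests run at deliberately modest sizes — six
strains, ~300 nt barcode units, ~12 repeats per genome, 20 kb background
assemblies, 20-replicate contrasts — chosen so that the full analysis
reruns from scratch in a few minutes on one core while leaving every
qualitative regime (gap present/absent, treelike/reticulate,
complete/truncate) clearly expressed.

## Known limitations

* The accession-based quantities reported for the real clade (ambiguity
  counts of deposited records, clone-set maxima, database distances,
  genome-mining counts) require the deposited GenBank records and
  assemblies; the package implements the computations but does not ship
  the records.
* Neighbour-net's circular ordering is taken from the established
  implementation; no independent second implementation of the
  agglomeration is bundled, though its output is validated against exact
  constructions (tree metrics, box metrics) where the answer is known.
* The delta score is reported per matrix without block-resampling
  uncertainty; matched-config comparisons are the supported way to draw
  conclusions from it.
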