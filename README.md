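# rdnadiv — diagnosing DNA barcode failure from multicopy rDNA diversity

DNA barcoding rests on the *barcode gap*: for a pair of species A and B,

```
gap(A, B) = min d(a, b)  −  max( max d(a, a'), max d(b, b') )
            a∈A, b∈B          a,a'∈A          b,b'∈B
```

with `d` the uncorrected percent distance. A positive gap means the barcode
separates the species. In yeasts the primary barcodes (ITS, LSU D1/D2) sit
on the multicopy rDNA, and the premise holds only while concerted evolution
keeps a genome's repeat copies homogeneous. In the *Metschnikowia
pulcherrima* clade it does not: rDNA units are dispersed across chimeric
(admixed) genomes, escape homogenization, diverge by birth-and-death
turnover, and the intragenomic diversity rivals the interstrain diversity —
so the gap vanishes and barcodes stop identifying species.

`rdnadiv` is an R package plus analysis workflow for diagnosing exactly
this failure mode, aimed at yeast taxonomists and anyone working with
heterogeneous multicopy markers. It provides:

* **uncorrected pairwise distances** with explicit ambiguity policies
  (strict vs IUPAC set-overlap), intragenomic/interstrain partitions,
  distance histograms and per-pair barcode-gap verdicts;
* **secondary-structure-aware site classification** — variable (SND)
  columns classified as unpaired-neutral, wobble/hemi-CBC, compensatory
  base change (CBC) or mismatch, with pseudogene flagging of sequences
  that break designated CBC pairs;
* **trees and split networks** — deterministic neighbour joining,
  neighbour-net circular split systems with non-negative least-squares
  split weights (NEXUS export for split-network viewers), and quartet
  delta scores / Q-residuals quantifying how non-treelike the data are;
* **repeat mining** — seed-and-extend local search for barcode units and
  gene copies in assemblies, complete/truncate classification, per-contig
  repeat tables, haplotype grouping, and the admixture verdict
  (intragenomic gene-copy differences exceeding between-genome ones);
* **polymorphic consensus barcodes** — IUPAC consensus with di-, tri- and
  tetramorphic sites, majority consensus, and an in-silico Sanger read
  with a minor-variant detection threshold;
* **a forward simulator** of repeat evolution under homogenization,
  birth-and-death and hybrid admixture, which generates every input above
  with ground-truth labels and powers the validation suite.

## Worked example

Simulate the admixed regime (dispersed repeats, late hybridization between
`st1` and `st3` with mosaic block retention), then ask whether the barcode
still separates the strains:

```r
library(rdnadiv)

cfg <- read_simulation_config(system.file("extdata", "configs",
                                          "admixed.yaml", package = "rdnadiv"))
ds  <- simulate_dataset(cfg)
dm  <- distance_matrix(alignment(ds$clones), policy = "strict")

head(barcode_gap_report(dm, ds$taxon_map), 4)
#>   taxon_a taxon_b max_intra_a max_intra_b min_inter   gap gap_present
#> 1     st1     st2        6.33        6.00      1.67 -4.67       FALSE
#> 2     st1     st3        6.33        5.67      0.00 -6.33       FALSE
#> 3     st1     st4        6.33        5.67      2.00 -4.33       FALSE
#> 4     st1     st5        6.33        6.67      1.67 -5.00       FALSE

delta_score(dm)
#> mean delta score 0.1274 over 635376 quartets; Q-residual 0.002295
```

Within-strain clone distances reach 6.7% while the closest clones of
different strains are identical (`min_inter` 0% for the hybridizing pair):
every gap is negative, so no pair of strains is barcode-separable — the
hybrid pair most drastically. The delta score over all clone quartets is
far from the additive value 0, the signature of reticulate, non-treelike
evolution. The same strain's repeat pool can still be *represented*, just
not by any single sequence:

```r
sub <- ds$clones[ds$clones$taxon == "st1", ]
cons <- iupac_consensus(alignment(sub), min_proportion = 0.2)
count_ambiguous_positions(cons$record)
#> [1] 8
```

eight di-/trimorphic IUPAC positions in the polymorphic consensus barcode
of `st1`.

## The analysis workflow

The numbered scripts under `analysis/` rerun the whole study on simulated
conditions and write tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | builds the three regimes (birth-and-death, homogenized, admixed) and emits genomes, clones, Sanger reads, structure, truth tables |
| `02_barcode_gap.R` | distance matrices, intragenomic/interstrain histograms, gap reports per regime |
| `03_site_structure.R` | variable sites vs structure, substitution classes, pseudogene flags scored against truth |
| `04_reticulation.R` | NJ trees, neighbour-net splits (NEXUS/TSV), delta scores, matched hybridization-on/off comparison |
| `05_repeat_mining.R` | seed-and-extend scans of the assemblies, complete/truncate tables, haplotype groups |
| `06_consensus_barcodes.R` | polymorphic IUPAC consensus per strain, Sanger emulation, ambiguity summary |

Run them in order from the repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

## Scope notes

Distances are uncorrected only (no model correction); structures are
inputs, never predicted; no maximum-likelihood trees, statistical-parsimony
networks, bootstrap, or remote database searches. The methods vignette
(`vignettes/barcode-failure-diagnosis.Rmd`) documents the models,
parameter defaults, numerical conventions and known limitations in detail.
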