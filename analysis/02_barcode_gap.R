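#!/usr/bin/env Rscript
# Intragenomic vs interstrain barcode diversity and the barcode gap.
# Reads the cloned sequences emitted by 01_simulate.R, computes uncorrected
# pairwise distances, partitions them within/between strains, bins them as
# in a barcode-gap histogram, and writes the per-pair gap verdicts.

suppressMessages(library(rdnadiv))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

for (regime in c("birthdeath", "homogenized", "admixed")) {
  dir <- file.path("results/data", regime)
  clones <- read_fasta(file.path(dir, "clones.fasta"))
  tmap <- read_taxon_map(file.path(dir, "taxon_map.tsv"))
  aln <- alignment(clones)
  dm <- distance_matrix(aln, policy = "strict")
  write_phylip_dist(dm, file.path("results/tables",
                                  paste0(regime, "_distances.phy")))
  part <- intra_inter_partition(dm, tmap)
  hist_all <- rbind(
    cbind(kind = "intragenomic",
          distance_histogram(unlist(part$intra), 0.5)),
    cbind(kind = "interstrain",
          distance_histogram(unlist(part$inter), 0.5)))
  write.table(hist_all, file.path("results/tables",
                                  paste0(regime, "_distance_histogram.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- barcode_gap_report(dm, tmap)
  write.table(rep, file.path("results/tables", paste0(regime, "_gap_report.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%-11s max intra %.2f%%  min inter %.2f%%  gap present %d/%d pairs\n",
    regime, max(part$max_intra), min(part$min_inter),
    sum(rep$gap_present), nrow(rep)))
}
cat("the birth-and-death and admixed regimes lose the barcode gap;\n")
cat("only strong homogenization keeps species separable\n")
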