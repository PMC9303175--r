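#!/usr/bin/env Rscript
# Mine the simulated assemblies for barcode units by seed-and-extend local
# search, classify complete vs truncate repeats, tabulate their dispersed
# locations, and group the mined full-length units into haplotypes.

suppressMessages(library(rdnadiv))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
dir <- "results/data/birthdeath"

struct <- read_dotbracket(file.path(dir, "structure.dbn"))
query <- seq_records("barcode_unit", chartr("U", "T", struct$reference))
placements <- read.delim(file.path(dir, "placements.tsv"))

all_hits <- list()
for (fa in list.files(dir, pattern = "_genome\\.fasta$", full.names = TRUE)) {
  tx <- sub("_genome\\.fasta$", "", basename(fa))
  genome <- read_fasta(fa, source = "genome")
  hits <- classify_completeness(scan_genome(genome, query), threshold = 0.90)
  hits$taxon <- tx
  all_hits[[tx]] <- hits
  truth_n <- sum(placements$taxon == tx & placements$kind == "repeat")
  cat(sprintf("%s: %d repeat units found (%d planted), %d complete / %d truncate\n",
              tx, nrow(hits), truth_n,
              sum(hits$completeness == "complete"),
              sum(hits$completeness == "truncate")))
}
hits <- do.call(rbind, all_hits)
write_hits_tsv(hits, "results/tables/repeat_hits.tsv")
tab <- repeat_table(hits)
write.table(tab, "results/tables/repeat_locations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# haplotype structure of the mined full-length units of one strain
tx <- names(all_hits)[1]
full <- all_hits[[tx]][all_hits[[tx]]$completeness == "complete", ]
genome <- read_fasta(file.path(dir, paste0(tx, "_genome.fasta")),
                     source = "genome")
units <- vapply(seq_len(nrow(full)), function(i) {
  s <- substr(genome$residues[genome$id == full$contig[i]],
              full$start[i], full$end[i])
  if (full$strand[i] == "-") rdnadiv:::revcomp(s) else s
}, "")
same_len <- nchar(units) == max(table(nchar(units)) |> names() |> as.integer())
hg <- haplotype_groups(seq_records(sprintf("%s_unit%02d", tx,
                                           seq_along(units))[same_len],
                                   units[same_len]))
cat(sprintf("%s: %d full-length units fall into %d haplotype group(s)\n",
            tx, sum(same_len), length(hg$groups)))
if (nrow(hg$distinguishing)) {
  cat("distinguishing positions between groups:\n")
  print(hg$distinguishing)
}
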