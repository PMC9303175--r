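#!/usr/bin/env Rscript
# Variable alignment sites read against the secondary structure: where the
# variation sits (loops vs stems), which substitution classes dominate, and
# which sequences carry structure-breaking mismatches at designated
# compensatory (CBC) pairs, i.e. putative pseudogenes.

suppressMessages(library(rdnadiv))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
dir <- "results/data/birthdeath"

clones <- read_fasta(file.path(dir, "clones.fasta"))
struct <- read_dotbracket(file.path(dir, "structure.dbn"))
truth <- read.delim(file.path(dir, "clones.tsv"))

aln <- alignment(clones)
ref <- which(!grepl("-", clones$residues))[1]
sites <- find_variable_sites(aln, struct, ref = ref)
write_site_report(sites, "results/tables/variable_sites.tsv")

anchored <- sites[sites$context %in% c("paired", "unpaired"), ]
cat(sprintf("%d variable sites (%d SND/dimorphic); %.0f%% in unpaired segments (structure is %.0f%% unpaired)\n",
            nrow(sites), sum(sites$arity == "dimorphic"),
            100 * mean(anchored$context == "unpaired"),
            100 * mean(is.na(struct$partner))))
print(table(class = sites$subst_class))

rep <- flag_pseudogenes(aln, struct, sites, ref = ref)
write.table(rep$flags, "results/tables/pseudogene_flags.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
pred <- rep$flags$flagged[match(truth$id, rep$flags$id)]
tp <- sum(pred & truth$status == "pseudogene")
cat(sprintf("pseudogene flags: %d flagged; precision %.0f%%, recall %.0f%% against simulated truth\n",
            sum(pred), 100 * tp / max(1, sum(pred)),
            100 * tp / max(1, sum(truth$status == "pseudogene"))))
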