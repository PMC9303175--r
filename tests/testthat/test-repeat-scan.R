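test_that("a verbatim planted query is found once with exact coordinates", {
  set.seed(61)
  q <- rand_seq(300)
  fx <- plant_contig(4000, q)
  genome <- seq_records("ctg", fx$contig, source = "genome")
  hits <- scan_genome(genome, seq_records("unit", q))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, fx$truth$start)
  expect_equal(hits$end, fx$truth$end)
  expect_equal(hits$identity, 1)
  expect_equal(hits$coverage, 1)
  expect_error(scan_genome(genome, seq_records("short", "ACGTACG")),
               class = "rdnadiv_query_too_short")
})

test_that("diverged and truncated plants report identity and coverage faithfully", {
  set.seed(62)
  q <- rand_seq(300)
  div <- mutate_pct(q, 0.10)
  half <- substr(q, 151, 300)      # 5'-truncated
  fx <- plant_contig(6000, c(div, half))
  genome <- seq_records("ctg", fx$contig, source = "genome")
  hits <- classify_completeness(scan_genome(genome, seq_records("unit", q)))
  expect_equal(nrow(hits), 2)
  h1 <- hits[hits$start == fx$truth$start[1], ]
  expect_equal(h1$identity, 0.90, tolerance = 0.03)
  expect_equal(h1$completeness, "complete")
  h2 <- hits[abs(hits$start - fx$truth$start[2]) < 10, ]
  expect_equal(h2$coverage, 0.5, tolerance = 0.05)
  expect_equal(h2$completeness, "truncate")
})

test_that("scanning is strand-symmetric and hits never cross contig bounds", {
  set.seed(63)
  q <- rand_seq(250)
  fx <- plant_contig(5000, c(q, mutate_pct(q, 0.05)), strands = c("+", "-"))
  genome <- seq_records("ctg", fx$contig, source = "genome")
  hits <- scan_genome(genome, seq_records("unit", q))
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("+", "-"))
  expect_true(all(hits$start >= 1 & hits$end <= nchar(fx$contig)))
  # mirror: scan the reverse-complemented contig
  rcg <- seq_records("ctg", paste(rev(strsplit(chartr("ACGT", "TGCA", fx$contig),
                                               "")[[1]]), collapse = ""),
                     source = "genome")
  mirror <- scan_genome(rcg, seq_records("unit", q))
  expect_equal(nrow(mirror), 2)
  expect_setequal(nchar(fx$contig) - mirror$end + 1L, hits$start)
  expect_setequal(mirror$strand, c("-", "+"))
})

test_that("planted repeats are recovered completely across random replicates", {
  set.seed(64)
  for (rep in 1:15) {
    q <- rand_seq(200)
    plants <- c(mutate_pct(q, 0.05), mutate_pct(q, 0.05), mutate_pct(q, 0.10))
    fx <- plant_contig(4500, plants)
    genome <- seq_records("ctg", fx$contig, source = "genome")
    hits <- scan_genome(genome, seq_records("unit", q), min_identity = 0.85)
    expect_equal(nrow(hits), 3)           # 100% recall, no duplicates
    expect_true(all(sort(hits$start) == fx$truth$start))
  }
})

test_that("completeness classification uses a closed boundary", {
  h <- data.frame(contig = "c", start = 1L, end = 10L, strand = "+",
                  query = "q", identity = 1,
                  coverage = c(1, 0.5, 0.9), score = 1)
  cl <- classify_completeness(h, 0.9)
  expect_equal(cl$completeness, c("complete", "truncate", "complete"))
})

test_that("repeat tables tally complete/truncate per contig and in total", {
  h <- data.frame(contig = c("A", "A", "A", "B"),
                  start = c(1L, 100L, 200L, 1L), end = c(50L, 150L, 250L, 50L),
                  strand = "+", query = "ITS", identity = 1,
                  coverage = c(1, 1, 0.5, 1), score = 1)
  tab <- repeat_table(classify_completeness(h))
  rowA <- tab[tab$contig == "A", ]
  expect_equal(rowA$complete, 2L)
  expect_equal(rowA$truncate, 1L)
  expect_equal(attr(tab, "totals")$complete, 3L)
  expect_equal(nrow(repeat_table(classify_completeness(h[0, ]))), 0)
})

test_that("repeat tables on simulated assemblies match planted truth", {
  ds <- simulate_dataset(simulation_config(seed = 19, n_repeats = 8,
                                           clones_per_strain = 6))
  tx <- ds$taxa[1]
  genome <- ds$assemblies[ds$assemblies$taxon == tx, ]
  q <- seq_records("unit", chartr("U", "T", ds$structure$reference))
  hits <- classify_completeness(scan_genome(genome, q))
  pl <- ds$truth$placements
  pl <- pl[pl$taxon == tx & pl$kind == "repeat", ]
  expect_equal(nrow(hits), nrow(pl))
  # every non-truncated plant is hit at exact coordinates
  full <- merge(pl, ds$truth$repeats[, c("repeat_id", "status")],
                by.x = "id", by.y = "repeat_id")
  intact <- full[full$status != "truncate", ]
  m <- merge(intact, as.data.frame(hits), by = c("contig", "start"))
  expect_equal(nrow(m), nrow(intact))
  expect_true(all(m$end.x == m$end.y))
})

test_that("haplotype grouping partitions sequences and counts distinguishing sites", {
  recs <- seq_records(c("a", "b", "c"), c("AAA", "AAA", "AAT"))
  hg <- haplotype_groups(recs)
  expect_length(hg$groups, 2)
  expect_equal(hg$distinguishing$positions, 1L)
  one <- haplotype_groups(seq_records(c("a", "b"), c("AAA", "AAA")))
  expect_length(one$groups, 1)
  expect_equal(nrow(one$distinguishing), 0)
  expect_error(haplotype_groups(seq_records(c("a", "b"), c("AAA", "AAAA"))),
               class = "rdnadiv_length_mismatch")
})

test_that("haplotype grouping resolves planted clusters at the link threshold", {
  set.seed(65)
  base <- rand_seq(120)
  centers <- c(base, mutate_pct(base, 5 / 120), mutate_pct(base, 10 / 120))
  seqs <- character(0)
  for (ci in 1:3) for (k in 1:4) {
    s <- centers[ci]
    if (k > 1) s <- mutate_pct(s, 1 / 120)    # one diff inside the cluster
    seqs <- c(seqs, s)
  }
  recs <- seq_records(sprintf("g%d_%d", rep(1:3, each = 4), rep(1:4, 3)), seqs)
  hg <- haplotype_groups(recs, merge_threshold = 2)
  expect_length(hg$groups, 3)
  # distinguishing counts equal an exhaustive consensus column scan
  cm <- do.call(rbind, strsplit(hg$consensus, ""))
  for (r in seq_len(nrow(hg$distinguishing))) {
    a <- hg$distinguishing$group_a[r]; b <- hg$distinguishing$group_b[r]
    expect_equal(hg$distinguishing$positions[r], sum(cm[a, ] != cm[b, ]))
  }
})

test_that("gene copy reports expose admixed (chimeric) gene origins", {
  set.seed(66)
  gene <- rand_seq(300)
  farA <- mutate_pct(gene, 0.04)       # counterpart in genome B, close to copy2
  copy1 <- gene
  copy2 <- mutate_pct(farA, 0.003)     # copy2 nearly identical to B's gene
  gA <- plant_contig(3000, c(copy1, copy2))
  gB <- plant_contig(3000, farA)
  genomes <- list(A = seq_records("A_ctg", gA$contig, source = "genome"),
                  B = seq_records("B_ctg", gB$contig, source = "genome"))
  rep <- gene_copy_report(genomes, seq_records("gene1", gene))
  expect_equal(unname(rep$counts["gene1", ]), c(2L, 1L), ignore_attr = TRUE)
  row <- rep$pairs[rep$pairs$genome == "A", ]
  expect_true(row$intra_exceeds_inter)
  # single copy: no intragenomic pairs
  expect_false("B" %in% rep$pairs$genome)
})
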