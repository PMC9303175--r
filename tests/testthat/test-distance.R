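test_that("pairwise distances follow the ambiguity policy and pairwise deletion", {
  expect_equal(pairwise_distance("ACGT", "ACGT")$differences, 0L)
  p <- pairwise_distance("AAAA", "AAAT")
  expect_equal(p$differences, 1L)
  expect_equal(p$compared_sites, 4L)
  expect_equal(p$percent, 25)
  # strict counts an ambiguity overlap as a difference, set-overlap does not
  expect_equal(pairwise_distance("AR", "AA", policy = "strict")$differences, 1L)
  expect_equal(pairwise_distance("AR", "AA", policy = "set-overlap")$differences, 0L)
  # gaps (and N by default) are excluded sites
  expect_equal(pairwise_distance("A-GT", "AAGT")$compared_sites, 3L)
  expect_equal(pairwise_distance("ANGT", "AAGT")$compared_sites, 3L)
  expect_equal(pairwise_distance("ANGT", "AAGT", exclude_n = FALSE)$compared_sites, 4L)
  expect_error(pairwise_distance("AC", "ACG"), class = "rdnadiv_length_mismatch")
  expect_error(pairwise_distance("--", "AC"), class = "rdnadiv_undefined_distance")
})

test_that("strict distance dominates set-overlap and deletion is monotone", {
  set.seed(7)
  syms <- c("A", "C", "G", "T", "R", "Y", "N", "-")
  for (i in 1:25) {
    a <- paste(sample(syms, 30, replace = TRUE), collapse = "")
    b <- paste(sample(syms, 30, replace = TRUE), collapse = "")
    ok <- tryCatch({
      s <- pairwise_distance(a, b, "strict")
      o <- pairwise_distance(a, b, "set-overlap")
      expect_gte(s$differences, o$differences)
      expect_equal(s$compared_sites, o$compared_sites)
      # adding a gap never increases compared sites
      a2 <- sub("[ACGT]", "-", a)
      s2 <- pairwise_distance(a2, b, "strict")
      expect_lte(s2$compared_sites, s$compared_sites)
      TRUE
    }, rdnadiv_undefined_distance = function(e) TRUE)
    expect_true(ok)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and match a brute-force oracle", {
  recs <- seq_records(c("x", "y", "z"), c("AAAA", "AAAT", "AATT"))
  dm <- distance_matrix(alignment(recs))
  expect_equal(sort(dm[upper.tri(dm)]), c(25, 25, 50))
  set.seed(11)
  n <- 20
  rows <- replicate(n, rand_seq(60))
  aln <- alignment(seq_records(sprintf("s%02d", 1:n), rows))
  dm <- distance_matrix(aln)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  # independent double-loop oracle over raw strings
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ca <- strsplit(rows[i], "")[[1]]; cb <- strsplit(rows[j], "")[[1]]
    expect_equal(dm[i, j], 100 * sum(ca != cb) / 60)
  }
})

test_that("intra/inter partition covers each pair exactly once", {
  recs <- seq_records(c("a1", "a2", "b1", "b2"),
                      c("AAAA", "AAAT", "TTAA", "TTTT"))
  tmap <- data.frame(id = recs$id, taxon = c("A", "A", "B", "B"))
  dm <- distance_matrix(alignment(recs))
  part <- intra_inter_partition(dm, tmap)
  expect_length(part$intra$A, 1)
  expect_length(part$intra$B, 1)
  expect_length(part$inter[["A|B"]], 4)
  expect_equal(length(unlist(part$intra)) + length(unlist(part$inter)), choose(4, 2))
  # exhaustive-scan oracle for maxima and minima
  expect_equal(part$max_intra[["A"]], dm["a1", "a2"])
  expect_equal(part$min_inter[["A|B"]],
               min(dm[c("a1", "a2"), c("b1", "b2")]))
  expect_error(intra_inter_partition(dm, tmap[-1, ]),
               class = "rdnadiv_unmapped_label")
  # single taxon: empty inter partition
  one <- intra_inter_partition(dm, data.frame(id = recs$id, taxon = "A"))
  expect_length(one$inter, 0)
})

test_that("barcode gap arithmetic and verdicts are exact", {
  # intra maxima 1% and 2%, min inter 5% -> gap 3
  recs <- seq_records(
    c("a1", "a2", "b1", "b2"),
    c(paste(rep("A", 100), collapse = ""),
      paste(c(rep("A", 99), "T"), collapse = ""),                 # 1% from a1
      paste(c(rep("C", 5), rep("A", 95)), collapse = ""),         # 5% from a1
      paste(c(rep("C", 5), rep("A", 93), "G", "G"), collapse = "")))
  tmap <- data.frame(id = recs$id, taxon = c("A", "A", "B", "B"))
  rep <- barcode_gap_report(distance_matrix(alignment(recs)), tmap)
  expect_equal(rep$gap, 3)
  expect_true(rep$gap_present)
  # negative gap
  recs2 <- seq_records(
    c("a1", "a2", "b1", "b2"),
    c(paste(rep("A", 100), collapse = ""),
      paste(c(rep("T", 6), rep("A", 94)), collapse = ""),         # intra 6%
      paste(c(rep("C", 5), rep("A", 95)), collapse = ""),
      paste(c(rep("C", 5), rep("A", 95)), collapse = "")))
  rep2 <- barcode_gap_report(distance_matrix(alignment(recs2)), tmap)
  expect_equal(rep2$gap, -1)
  expect_false(rep2$gap_present)
  # singleton taxa flagged with undefined intra
  tmap3 <- data.frame(id = recs$id, taxon = c("A", "A", "B", "C"))
  rep3 <- barcode_gap_report(distance_matrix(alignment(recs)), tmap3)
  expect_true(all(rep3$singleton[rep3$taxon_b %in% c("B", "C")]))
  expect_true(anyNA(rep3$gap))
})

test_that("similarity filtering retains candidates within the percent threshold", {
  set.seed(5)
  q <- rand_seq(200)
  cands <- seq_records(
    sprintf("c%02d", 1:10),
    vapply(seq(0.01, 0.10, by = 0.01), function(p) mutate_pct(q, p), ""))
  kept <- similarity_filter(seq_records("q", q), cands, max_percent = 5)
  expect_equal(kept$id, sprintf("c%02d", 1:5))
  expect_true(all(kept$percent <= 5))
  # identical query among diverged candidates
  cands2 <- seq_records(c("self", "far1", "far2"),
                        c(q, mutate_pct(q, 0.10), mutate_pct(q, 0.10)))
  expect_equal(similarity_filter(seq_records("q", q), cands2, 5)$id, "self")
  # threshold 0 keeps ambiguity-compatible matches under set-overlap
  amb <- sub("A", "R", q)
  expect_equal(nrow(similarity_filter(seq_records("q", q),
                                      seq_records("amb", amb), 0)), 1)
})

test_that("distance histograms bin left-closed from zero and conserve counts", {
  h <- distance_histogram(c(0, 1, 1, 2), 1)
  expect_equal(h$count, c(1L, 2L, 1L))
  expect_equal(h$lower, c(0, 1, 2))
  expect_equal(nrow(distance_histogram(numeric(0), 1)), 0)
  expect_error(distance_histogram(1:3, 0), class = "rdnadiv_bad_bin_width")
  set.seed(2)
  v <- runif(500, 0, 30)
  expect_equal(sum(distance_histogram(v, 2.5)$count), 500L)
})

test_that("the barcode gap shrinks as intragenomic diversity grows", {
  # homogenization suppresses within-genome diversity; lowering it (all else
  # fixed, same seed) raises the intragenomic mutation load and must never
  # widen the gap
  gaps <- vapply(c(0, 10, 100), function(h) {
    cfg <- simulation_config(seed = 11, placement = "arrayed",
                             homogenization_rate = h, birth_rate = 0.1,
                             death_rate = 0.05, truncation_rate = 0.02)
    ds <- simulate_dataset(cfg)
    dm <- distance_matrix(alignment(ds$clones))
    mean(barcode_gap_report(dm, ds$taxon_map)$gap)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))  # gap grows with homogenization
})
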