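test_that("dot-bracket parsing builds an involutive partner map", {
  s <- parse_dotbracket("GGGAAACCC", "(((...)))")
  expect_equal(s$pairs[order(s$pairs[, 1]), ],
               cbind(1:3, 9:7), ignore_attr = TRUE)
  expect_equal(nrow(parse_dotbracket("AAAA", "....")$pairs), 0)
  expect_error(parse_dotbracket("GGGAAAC", "(((..))"),
               class = "rdnadiv_unbalanced_structure")
  expect_error(parse_dotbracket("GGG", "(((..)))"),
               class = "rdnadiv_length_mismatch")
  # involution over a multi-tier structure
  s2 <- parse_dotbracket(paste(rep("A", 12), collapse = ""), "((.[[..]].))")
  p <- s2$partner
  for (i in which(!is.na(p))) expect_equal(p[p[i]], i)
})

test_that("variable-site detection applies the minor-count rule and class vocabulary", {
  # column 5: A:7 / G:3 (purine transition); column 10: C:8 / T:2 (below default)
  base <- strsplit(paste(rep("ACGTACGTAC", 1), collapse = ""), "")[[1]]
  rows <- replicate(10, base, simplify = FALSE)
  for (i in 1:3) rows[[i]][5] <- "G"
  for (i in 1:2) rows[[i]][10] <- "T"
  recs <- seq_records(sprintf("s%02d", 1:10),
                      vapply(rows, paste, "", collapse = ""))
  aln <- alignment(recs)
  sites <- find_variable_sites(aln, min_minor_count = 3)
  expect_equal(sites$column, 5L)
  expect_equal(sites$subst_class, "purine transition")
  expect_equal(sites$arity, "dimorphic")
  # the near-variable column appears when the threshold is lowered
  sites2 <- find_variable_sites(aln, min_minor_count = 2)
  expect_setequal(sites2$column, c(5L, 10L))
  expect_equal(sites2$subst_class[sites2$column == 10L], "pyrimidine transition")
  # classification is invariant under row reordering
  perm <- sample(nrow(recs))
  sites3 <- find_variable_sites(alignment(recs[perm, ]), min_minor_count = 3,
                                ref = which(perm == 1))
  expect_equal(sites3$column, sites$column)
  expect_equal(sites3$subst_class, sites$subst_class)
})

test_that("pairing-effect classes match a hand-enumerated oracle", {
  bases <- c("A", "C", "G", "U")
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  # all 16 invariant (site, partner) combinations
  for (s in bases) for (p in bases) {
    got <- classify_pairing_effect(rep(s, 6), rep(p, 6))
    want <- if (paste0(s, p) %in% canonical) "wobble_neutral" else "mismatch"
    expect_equal(got$effect, want, info = paste(s, p))
  }
  # all two-state covariation patterns: sequences split between combo 1 and 2
  combos <- as.vector(outer(bases, bases, paste0))
  for (c1 in combos) for (c2 in combos) {
    if (c1 >= c2) next
    s <- c(rep(substr(c1, 1, 1), 4), rep(substr(c2, 1, 1), 4))
    p <- c(rep(substr(c1, 2, 2), 4), rep(substr(c2, 2, 2), 4))
    got <- classify_pairing_effect(s, p)$effect
    want <- if (!all(c(c1, c2) %in% canonical)) "mismatch"
      else if (substr(c1, 1, 1) != substr(c2, 1, 1) &&
               substr(c1, 2, 2) != substr(c2, 2, 2)) "CBC"
      else "wobble_neutral"
    expect_equal(got, want, info = paste(c1, c2))
  }
  # named examples: G partner with C/U alternation is wobble-neutral;
  # (G,C) vs (A,U) is a CBC; (A,C) is pseudogene-grade mismatch
  expect_equal(classify_pairing_effect(c("C", "C", "U", "U"),
                                       c("G", "G", "G", "G"))$effect,
               "wobble_neutral")
  expect_equal(classify_pairing_effect(c("G", "G", "A", "A"),
                                       c("C", "C", "U", "U"))$effect, "CBC")
  expect_equal(classify_pairing_effect(c("A", "G"), c("C", "C"))$effect,
               "mismatch")
})

test_that("classification is invariant under T/U representation", {
  expect_equal(classify_pairing_effect(c("C", "T", "T"), c("G", "G", "G"))$effect,
               classify_pairing_effect(c("C", "U", "U"), c("G", "G", "G"))$effect)
})

test_that("with an empty pair set every variable site is unpaired-neutral", {
  set.seed(4)
  L <- 30
  base <- strsplit(rand_seq(L), "")[[1]]
  rows <- replicate(8, base, simplify = FALSE)
  for (i in 1:4) rows[[i]][10] <- setdiff(c("A", "C", "G", "T"), base[10])[1]
  recs <- seq_records(sprintf("s%d", 1:8), vapply(rows, paste, "", collapse = ""))
  str0 <- parse_dotbracket(paste(base, collapse = ""),
                           paste(rep(".", L), collapse = ""))
  sites <- find_variable_sites(alignment(recs), str0)
  expect_true(all(sites$pairing_effect == "neutral_unpaired"))
})

test_that("pseudogene flags cite broken pairs and region fractions are exact", {
  # stem of 3 pairs: positions 1-3 pair 10-8; one row breaks a pair
  seqs <- c("GGGAAAACCC", "GGGAAAACCC", "GGGAAAACCC", "GGGAAAACCC",
            "GGGAAAACCA")  # row 5: position 10 pairs position 1 (G) -> G,A bad
  recs <- seq_records(sprintf("s%d", 1:5), seqs)
  aln <- alignment(recs,
                   regions = data.frame(name = c("stemL", "loop"),
                                        start = c(1L, 4L), end = c(3L, 7L)))
  struct <- parse_dotbracket(seqs[1], "(((....)))",
                             cbc_pairs = cbind(1L, 10L))
  sites <- find_variable_sites(aln, struct, min_minor_count = 1)
  rep <- flag_pseudogenes(aln, struct, sites)
  expect_equal(rep$flags$flagged, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_match(rep$flags$reasons[5], "pair 1-10")
  expect_equal(rep$region_variability$fraction,
               c(0, 0))  # the variable column (10) is outside both regions
  # all-canonical alignment: no flags
  aln0 <- alignment(recs[1:4, ])
  rep0 <- flag_pseudogenes(aln0, struct, find_variable_sites(aln0, struct))
  expect_equal(sum(rep0$flags$flagged), 0)
})

test_that("region variability fractions count variable columns exactly", {
  set.seed(9)
  L <- 40
  base <- strsplit(rand_seq(L), "")[[1]]
  rows <- replicate(10, base, simplify = FALSE)
  vcols <- c(3L, 7L, 25L)
  for (cc in vcols) for (i in 1:5) {
    rows[[i]][cc] <- setdiff(c("A", "C", "G", "T"), base[cc])[1]
  }
  recs <- seq_records(sprintf("s%02d", 1:10),
                      vapply(rows, paste, "", collapse = ""))
  aln <- alignment(recs, regions = data.frame(name = c("r1", "r2"),
                                              start = c(1L, 21L),
                                              end = c(20L, 40L)))
  struct <- parse_dotbracket(paste(base, collapse = ""),
                             paste(rep(".", L), collapse = ""))
  sites <- find_variable_sites(aln, struct)
  rep <- flag_pseudogenes(aln, struct, sites)
  expect_equal(rep$region_variability$fraction, c(2 / 20, 1 / 20))
  expect_true(all(rep$region_variability$fraction >= 0 &
                    rep$region_variability$fraction <= 1))
})

test_that("dot-bracket files round-trip including CBC designations", {
  s <- parse_dotbracket("GGGAAACCC", "(((...)))", cbc_pairs = cbind(2L, 8L))
  p <- withr::local_tempfile(fileext = ".dbn")
  write_dotbracket(s, p)
  back <- read_dotbracket(p)
  expect_equal(back$partner, s$partner)
  expect_equal(back$cbc_pairs, s$cbc_pairs, ignore_attr = TRUE)
  expect_equal(back$reference, s$reference)
})
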