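# shared fixture builders; everything is generated in code at test time

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

# substitute a given fraction of positions (never to the same base)
mutate_pct <- function(s, pct) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- sample(length(chars), round(pct * length(chars)))
  for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

# random unrooted tree with positive branch lengths and its additive matrix
random_additive <- function(n, min_len = 0.1, max_len = 1) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  list(tree = tr, dm = stats::cophenetic(tr))
}

# metric that is the sum of two incompatible splits of equal weight (a "box")
box_metric <- function(w = 0.7) {
  taxa <- c("a", "b", "c", "d")
  s1 <- c(TRUE, TRUE, FALSE, FALSE)   # ab | cd
  s2 <- c(FALSE, TRUE, TRUE, FALSE)   # bc | ad
  dm <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  for (i in 1:4) for (j in 1:4) {
    dm[i, j] <- w * (s1[i] != s1[j]) + w * (s2[i] != s2[j])
  }
  dm
}

# build a contig with sequences planted at known positions; returns the
# contig string and a coordinate table (1-based inclusive)
plant_contig <- function(background_len, inserts, strands = NULL) {
  n <- length(inserts)
  if (is.null(strands)) strands <- rep("+", n)
  gap <- background_len %/% (n + 1L)
  chunks <- character(0)
  coord <- 0L
  rows <- list()
  for (i in seq_len(n)) {
    bg <- rand_seq(gap)
    chunks <- c(chunks, bg)
    coord <- coord + nchar(bg)
    ins <- if (strands[i] == "-") {
      paste(rev(strsplit(chartr("ACGT", "TGCA", inserts[i]), "")[[1]]), collapse = "")
    } else inserts[i]
    chunks <- c(chunks, ins)
    rows[[i]] <- data.frame(start = coord + 1L, end = coord + nchar(ins),
                            strand = strands[i])
    coord <- coord + nchar(ins)
  }
  chunks <- c(chunks, rand_seq(gap))
  list(contig = paste(chunks, collapse = ""), truth = do.call(rbind, rows))
}

# simulation config fixtures shipped with the package
fixture_config <- function(name) {
  read_simulation_config(system.file("extdata", "configs",
                                     paste0(name, ".yaml"),
                                     package = "rdnadiv", mustWork = TRUE))
}
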