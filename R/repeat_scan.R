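# Seed-and-extend mining of rDNA barcode units and gene copies in genome
# assemblies. Shared k-mers between query and contig seed candidate loci;
# each locus is then aligned (local, with a full-query refinement pass for
# near-complete hits) to obtain identity, query coverage and coordinates.
# Hits are classified complete/truncate by query coverage -- dispersed,
# partly decayed repeats are the expected signal in non-homogenized rDNA.

.sub_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# seed positions of query k-mers in a contig -> candidate windows
.seed_clusters <- function(contig, query, k) {
  Lg <- nchar(contig); Lq <- nchar(query)
  if (Lg < k) return(integer(0))
  g_kmers <- substring(contig, 1:(Lg - k + 1L), k:Lg)
  q_kmers <- substring(query, 1:(Lq - k + 1L), k:Lq)
  hit <- match(g_kmers, q_kmers)
  gpos <- which(!is.na(hit))
  if (!length(gpos)) return(list())
  # anchor = implied query start position in contig coordinates
  anchor <- gpos - (hit[gpos] - 1L)
  o <- order(anchor)
  anchor <- anchor[o]
  breaks <- c(0L, which(diff(anchor) > Lq), length(anchor))
  lapply(seq_len(length(breaks) - 1L), function(b) {
    anchor[(breaks[b] + 1L):breaks[b + 1L]]
  })
}

# align query against a window of the contig; returns hit row or NULL
.extend_hit <- function(contig, query, win_start, win_end, min_identity,
                        min_coverage) {
  win <- substr(contig, win_start, win_end)
  sm <- .sub_mat()
  al <- Biostrings::pairwiseAlignment(query, win, type = "local",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 2)
  alen <- Biostrings::nchar(al)
  if (alen == 0L) return(NULL)
  ident <- Biostrings::nmatch(al) / alen
  qcov <- (Biostrings::width(Biostrings::pattern(al))) / nchar(query)
  s0 <- win_start + Biostrings::start(Biostrings::subject(al)) - 1L
  e0 <- win_start + Biostrings::end(Biostrings::subject(al)) - 1L
  score <- Biostrings::score(al)
  if (qcov >= 0.75) {
    # near-complete: re-align with the whole query so that terminal
    # substitutions stay inside the hit and coordinates cover the full unit
    al2 <- Biostrings::pairwiseAlignment(query, win, type = "global-local",
                                         substitutionMatrix = sm,
                                         gapOpening = 0, gapExtension = 2)
    ident2 <- Biostrings::nmatch(al2) / Biostrings::nchar(al2)
    # accept the full-query refinement only when it does not degrade the
    # alignment (a genuinely truncated unit would force its missing part
    # onto background sequence and identity would drop)
    if (ident2 >= min_identity && ident2 >= ident - 0.02) {
      s0 <- win_start + Biostrings::start(Biostrings::subject(al2)) - 1L
      e0 <- win_start + Biostrings::end(Biostrings::subject(al2)) - 1L
      ident <- ident2
      qcov <- 1
      score <- Biostrings::score(al2)
    }
  }
  if (ident < min_identity || qcov < min_coverage) return(NULL)
  list(start = s0, end = e0, identity = ident, coverage = qcov, score = score)
}

#' Scan genome contigs for occurrences of a query sequence
#'
#' Bespoke seed-and-extend local search: k-mer seeds locate candidate loci
#' on both strands, a local alignment scores each locus, and same-strand
#' hits closer than `merge_gap` are merged keeping the higher-scoring
#' extension.
#'
#' @param genome `seq_records` of contigs.
#' @param query single-row `seq_records` (or residue string) to search for
#'   (e.g. an ITS or D1/D2 unit, or a gene coding region).
#' @param k seed k-mer length (default 12; the query must not be shorter).
#' @param min_identity minimum alignment identity to report (default 0.80).
#' @param min_coverage minimum query coverage to report (default 0.30).
#' @param merge_gap same-strand hits for the same query within this many bp
#'   are merged (default 50).
#' @param query_name label recorded in the hit table.
#' @return data frame of hits (class `repeat_hits`): `contig`, `start`,
#'   `end` (1-based inclusive), `strand`, `query`, `identity`, `coverage`,
#'   `score`, sorted by (contig, start).
#' @export
scan_genome <- function(genome, query, k = 12L, min_identity = 0.80,
                        min_coverage = 0.30, merge_gap = 50L,
                        query_name = NULL) {
  if (is.data.frame(query)) {
    if (is.null(query_name)) query_name <- query$id[1]
    query <- query$residues[1]
  }
  if (is.null(query_name)) query_name <- "query"
  query <- gsub("-", "", query, fixed = TRUE)
  if (nchar(query) < k) {
    .rdnadiv_error("rdnadiv_query_too_short",
                   sprintf("query (%d nt) shorter than seed length %d",
                           nchar(query), k))
  }
  Lq <- nchar(query)
  rows <- list()
  for (ci in seq_len(nrow(genome))) {
    contig <- genome$residues[ci]
    cname <- genome$id[ci]
    Lg <- nchar(contig)
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") query else revcomp(query)
      clusters <- .seed_clusters(contig, qseq, k)
      for (anchors in clusters) {
        win_start <- max(1L, min(anchors) - Lq %/% 2L)
        win_end <- min(Lg, max(anchors) + Lq + Lq %/% 2L)
        hit <- .extend_hit(contig, qseq, win_start, win_end,
                           min_identity, min_coverage)
        if (is.null(hit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cname, start = hit$start, end = hit$end, strand = strand,
          query = query_name, identity = hit$identity,
          coverage = hit$coverage, score = hit$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), query = character(0),
               identity = numeric(0), coverage = numeric(0),
               score = numeric(0), stringsAsFactors = FALSE)
  hits <- .merge_hits(hits, merge_gap)
  hits <- hits[order(hits$contig, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("repeat_hits", "data.frame")
  hits
}

# merge same-contig same-strand same-query hits whose intervals are within
# `gap` bp; the higher-scoring hit's alignment statistics are kept
.merge_hits <- function(hits, gap) {
  if (nrow(hits) < 2L) return(hits)
  key <- paste(hits$contig, hits$strand, hits$query, sep = "\r")
  out <- list()
  for (grp in split(hits, key)) {
    grp <- grp[order(grp$start), , drop = FALSE]
    cur <- grp[1, ]
    if (nrow(grp) > 1L) for (r in 2:nrow(grp)) {
      nxt <- grp[r, ]
      if (nxt$start <= cur$end + gap) {
        keep <- if (nxt$score > cur$score) nxt else cur
        keep$start <- min(cur$start, nxt$start)
        keep$end <- max(cur$end, nxt$end)
        cur <- keep
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify hits as complete or truncate by query coverage
#'
#' @param hits a `repeat_hits` data frame.
#' @param threshold coverage at or above which a hit is `complete`
#'   (default 0.90; the boundary is closed).
#' @return `hits` with a `completeness` column added; the threshold is
#'   recorded in the attribute `completeness_threshold`.
#' @export
classify_completeness <- function(hits, threshold = 0.90) {
  hits$completeness <- ifelse(hits$coverage >= threshold, "complete", "truncate")
  attr(hits, "completeness_threshold") <- threshold
  hits
}

#' Per-contig tally of complete and truncate hits per query
#'
#' @param hits classified hits (see [classify_completeness()]).
#' @return data frame with `contig`, `query`, `complete`, `truncate`
#'   counts; attribute `totals` holds the per-query grand totals.
#' @export
repeat_table <- function(hits) {
  if (nrow(hits) == 0L) {
    out <- data.frame(contig = character(0), query = character(0),
                      complete = integer(0), truncate = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "totals") <- out[, -1]
    return(out)
  }
  stopifnot("completeness" %in% names(hits))
  tab <- as.data.frame(table(contig = hits$contig, query = hits$query,
                             completeness = hits$completeness),
                       stringsAsFactors = FALSE)
  wide <- stats::reshape(tab, idvar = c("contig", "query"),
                         timevar = "completeness", direction = "wide")
  names(wide) <- sub("^Freq\\.", "", names(wide))
  for (col in c("complete", "truncate")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  wide <- wide[wide$complete + wide$truncate > 0, c("contig", "query", "complete", "truncate")]
  rownames(wide) <- NULL
  totals <- stats::aggregate(cbind(complete, truncate) ~ query, wide, sum)
  attr(wide, "totals") <- totals
  wide
}

#' Group aligned sequences into haplotypes
#'
#' Single-linkage grouping at a difference threshold (default 0: groups of
#' identical sequences). Distinguishing positions between two groups are
#' the columns where the group majority-consensus states differ; ties
#' within a group's column are broken towards the alphabetically first base
#' and logged in the attribute `ties`.
#'
#' @param seqs equal-length (aligned) `seq_records`.
#' @param merge_threshold maximum within-link difference count (default 0).
#' @return a `haplotype_grouping`: list with `groups` (list of id vectors),
#'   `assignment` (named integer vector), `distinguishing` (data frame per
#'   group pair with position counts) and `consensus` (per-group consensus
#'   strings).
#' @export
haplotype_groups <- function(seqs, merge_threshold = 0L) {
  n <- nrow(seqs)
  aln <- alignment(seqs)
  m <- aln_matrix(aln)
  if (n == 1L) {
    grp <- stats::setNames(1L, seqs$id)
  } else {
    dd <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dd[i, j] <- dd[j, i] <- sum(m[i, ] != m[j, ])
    }
    hc <- stats::hclust(stats::as.dist(dd), method = "single")
    grp <- stats::cutree(hc, h = merge_threshold + 0.5)
    names(grp) <- seqs$id
    # renumber groups by first appearance
    grp <- stats::setNames(match(grp, unique(grp)), seqs$id)
  }
  ngrp <- max(grp)
  ties <- character(0)
  cons <- vapply(seq_len(ngrp), function(g) {
    sub <- m[grp == g, , drop = FALSE]
    paste(apply(sub, 2, function(col) {
      tab <- sort(table(col), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) {
        ties <<- c(ties, paste0("group ", g))
        top <- sort(top)[1]
      }
      top[1]
    }), collapse = "")
  }, "")
  dist_rows <- list()
  if (ngrp > 1L) {
    cm <- do.call(rbind, strsplit(cons, "", fixed = TRUE))
    for (a in seq_len(ngrp - 1L)) for (b in (a + 1L):ngrp) {
      dist_rows[[length(dist_rows) + 1L]] <- data.frame(
        group_a = a, group_b = b,
        positions = sum(cm[a, ] != cm[b, ]))
    }
  }
  distinguishing <- if (length(dist_rows)) do.call(rbind, dist_rows) else
    data.frame(group_a = integer(0), group_b = integer(0), positions = integer(0))
  out <- list(groups = split(names(grp), grp), assignment = grp,
              distinguishing = distinguishing, consensus = cons,
              merge_threshold = merge_threshold)
  attr(out, "ties") <- ties
  class(out) <- "haplotype_grouping"
  out
}

#' @export
print.haplotype_grouping <- function(x, ...) {
  cat(sprintf("haplotype_grouping: %d sequences in %d group(s)\n",
              length(x$assignment), length(x$groups)))
  invisible(x)
}

# substitution count between two unaligned sequences after global alignment
.aligned_diff <- function(a, b) {
  sm <- .sub_mat()
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 2)
  pa <- as.character(Biostrings::alignedPattern(al))
  sa <- as.character(Biostrings::alignedSubject(al))
  pairwise_distance(pa, sa, policy = "strict")$differences
}

#' Copy counts and cross-genome similarity ranking for multi-copy genes
#'
#' For each gene query, each genome is scanned and the near-complete hits
#' counted as gene copies. For genomes with several copies the intragenomic
#' substitution counts are compared with the smallest distance to a copy in
#' any other genome: an intragenomic difference exceeding the closest
#' between-genome difference is the signature of admixed (hybrid) origin
#' rather than in-place duplication.
#'
#' @param genomes named list of `seq_records` (one per strain/assembly).
#' @param gene_queries `seq_records` of gene coding sequences.
#' @param min_identity,min_coverage passed to [scan_genome()]; copies are
#'   hits with coverage at or above `copy_coverage`.
#' @param copy_coverage coverage for a hit to count as a gene copy
#'   (default 0.90).
#' @param k seed length.
#' @return a `gene_copy_report`: list with `counts` (gene x genome copy
#'   matrix), `pairs` (per genome+gene intragenomic substitution counts,
#'   minimum intergenomic counts, and the admixture verdict
#'   `intra_exceeds_inter`), and `hits` (all raw hits).
#' @export
gene_copy_report <- function(genomes, gene_queries, min_identity = 0.80,
                             min_coverage = 0.30, copy_coverage = 0.90,
                             k = 12L) {
  stopifnot(!is.null(names(genomes)))
  all_hits <- list()
  copies <- list()  # copies[[gene]][[genome]] = character vector of sequences
  for (gi in seq_len(nrow(gene_queries))) {
    gname <- gene_queries$id[gi]
    copies[[gname]] <- list()
    for (gn in names(genomes)) {
      h <- scan_genome(genomes[[gn]], gene_queries[gi, ], k = k,
                       min_identity = min_identity,
                       min_coverage = min_coverage, query_name = gname)
      h <- classify_completeness(h, copy_coverage)
      if (nrow(h)) {
        h$genome <- gn
        all_hits[[length(all_hits) + 1L]] <- h
      }
      full <- h[h$completeness == "complete", , drop = FALSE]
      seqs <- character(0)
      if (nrow(full)) {
        seqs <- vapply(seq_len(nrow(full)), function(r) {
          s <- substr(genomes[[gn]]$residues[genomes[[gn]]$id == full$contig[r]],
                      full$start[r], full$end[r])
          if (full$strand[r] == "-") revcomp(s) else s
        }, "")
      }
      copies[[gname]][[gn]] <- seqs
    }
  }
  counts <- do.call(rbind, lapply(names(copies), function(g) {
    vapply(names(genomes), function(gn) length(copies[[g]][[gn]]), integer(1))
  }))
  rownames(counts) <- names(copies)
  pair_rows <- list()
  for (g in names(copies)) {
    for (gn in names(genomes)) {
      cp <- copies[[g]][[gn]]
      if (length(cp) < 2L) next
      intra <- utils::combn(length(cp), 2)
      intra_d <- apply(intra, 2, function(ij) .aligned_diff(cp[ij[1]], cp[ij[2]]))
      others <- unlist(copies[[g]][setdiff(names(genomes), gn)], use.names = FALSE)
      inter_min <- if (length(others)) {
        min(vapply(cp, function(a) {
          min(vapply(others, function(b) .aligned_diff(a, b), numeric(1)))
        }, numeric(1)))
      } else NA_real_
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        gene = g, genome = gn, n_copies = length(cp),
        max_intra = max(intra_d), min_intra = min(intra_d),
        min_inter = inter_min,
        intra_exceeds_inter = if (is.na(inter_min)) NA else max(intra_d) > inter_min,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(gene = character(0), genome = character(0), n_copies = integer(0),
               max_intra = numeric(0), min_intra = numeric(0),
               min_inter = numeric(0), intra_exceeds_inter = logical(0))
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else NULL
  structure(list(counts = counts, pairs = pairs, hits = hits,
                 copies = copies),
            class = "gene_copy_report")
}

#' @export
print.gene_copy_report <- function(x, ...) {
  cat("gene copy counts:\n")
  print(x$counts)
  invisible(x)
}

#' Write hits as a BED-like TSV
#'
#' Coordinates are written 1-based inclusive (as in the rest of the
#' package's human-readable output).
#'
#' @param hits a `repeat_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
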