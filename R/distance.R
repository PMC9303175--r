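# Uncorrected (p-) distances with pairwise deletion, the intragenomic /
# interstrain partition, and the barcode-gap statistic. Distances are raw
# difference counts over compared sites, as produced by distmat-style tools;
# no model correction is applied.

# logical 16x16(ish) lookup: do two IUPAC symbols share at least one base?
.OVERLAP <- local({
  syms <- setdiff(names(.IUPAC), "-")
  m <- matrix(FALSE, length(syms), length(syms), dimnames = list(syms, syms))
  for (a in syms) for (b in syms) {
    m[a, b] <- length(intersect(.IUPAC[[a]], .IUPAC[[b]])) > 0L
  }
  m
})

.policy_match <- function(policy) match.arg(policy, c("strict", "set-overlap"))

# core comparison of two character vectors (rows already split)
.pair_diff <- function(ca, cb, policy, exclude_n) {
  excluded <- ca == "-" | cb == "-"
  if (exclude_n) excluded <- excluded | ca == "N" | cb == "N"
  ca <- ca[!excluded]; cb <- cb[!excluded]
  compared <- length(ca)
  if (compared == 0L) {
    .rdnadiv_error("rdnadiv_undefined_distance",
                   "no comparable sites between the two rows (all gaps/excluded)")
  }
  if (policy == "strict") {
    diffs <- sum(ca != cb)
  } else {
    diffs <- sum(!.OVERLAP[cbind(ca, cb)])
  }
  list(differences = diffs, compared_sites = compared,
       percent = 100 * diffs / compared)
}

#' Uncorrected pairwise distance between two aligned sequences
#'
#' Positions where either row carries a gap (and, by default, `N`) are
#' excluded from the compared sites (pairwise deletion). A compared position
#' counts as a difference according to the ambiguity policy: `strict` (any
#' non-identical pair of symbols differs) or `set-overlap` (symbols differ
#' only when their IUPAC expansions share no base, so `A` vs `R` is not a
#' difference).
#'
#' @param a,b residues (single strings of equal length) or single-row
#'   `seq_records`.
#' @param policy `"strict"` or `"set-overlap"`.
#' @param exclude_n treat `N` like a gap (excluded site) rather than as an
#'   ambiguity symbol.
#' @return list with `id_a`, `id_b`, `differences`, `compared_sites`,
#'   `percent`.
#' @export
pairwise_distance <- function(a, b, policy = c("strict", "set-overlap"),
                              exclude_n = TRUE) {
  policy <- .policy_match(policy)
  id_a <- "a"; id_b <- "b"
  if (is.data.frame(a)) { id_a <- a$id[1]; a <- a$residues[1] }
  if (is.data.frame(b)) { id_b <- b$id[1]; b <- b$residues[1] }
  if (nchar(a) != nchar(b)) {
    .rdnadiv_error("rdnadiv_length_mismatch",
                   sprintf("rows differ in length (%d vs %d)", nchar(a), nchar(b)))
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  c(list(id_a = id_a, id_b = id_b), .pair_diff(ca, cb, policy, exclude_n))
}

#' Distance matrix over an alignment
#'
#' @param aln a `barcode_alignment`.
#' @param policy ambiguity policy, see [pairwise_distance()].
#' @param mode `"percent"` (default) or `"count"` (raw difference counts).
#' @param exclude_n treat `N` as an excluded site.
#' @return symmetric numeric matrix with zero diagonal, labelled by record
#'   ids; attributes `policy`, `mode`, `compared_sites` (matrix of per-pair
#'   compared-site counts) record the comparison settings.
#' @export
distance_matrix <- function(aln, policy = c("strict", "set-overlap"),
                            mode = c("percent", "count"), exclude_n = TRUE) {
  policy <- .policy_match(policy)
  mode <- match.arg(mode)
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) .rdnadiv_error("rdnadiv_too_few_rows", "need at least 2 rows")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  S <- matrix(nchar(aln$records$residues[1]), n, n,
              dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- .pair_diff(m[i, ], m[j, ], policy, exclude_n)
      v <- if (mode == "percent") p$percent else p$differences
      D[i, j] <- D[j, i] <- v
      S[i, j] <- S[j, i] <- p$compared_sites
    }
  }
  attr(D, "policy") <- policy
  attr(D, "mode") <- mode
  attr(D, "compared_sites") <- S
  D
}

# resolve a taxon map (data.frame id/taxon, named vector, or NULL -> records)
.taxon_lookup <- function(labels, taxon_map) {
  if (is.data.frame(taxon_map)) {
    tx <- taxon_map$taxon[match(labels, taxon_map$id)]
  } else {
    tx <- unname(taxon_map[labels])
  }
  if (any(is.na(tx) | tx == "")) {
    .rdnadiv_error("rdnadiv_unmapped_label",
                   sprintf("label '%s' has no taxon mapping",
                           labels[which(is.na(tx) | tx == "")[1]]))
  }
  tx
}

#' Partition pairwise distances into intra- and inter-taxon multisets
#'
#' Every unordered pair of sequences lands in exactly one multiset: the
#' within-taxon (intragenomic, when sequences are repeat clones of one
#' strain) multiset of its taxon, or the between-taxon multiset of its taxon
#' pair.
#'
#' @param dm distance matrix from [distance_matrix()].
#' @param taxon_map data frame (`id`, `taxon`) or named character vector
#'   mapping every matrix label to a taxon.
#' @return list with `intra` (named list of numeric vectors per taxon),
#'   `inter` (named list per taxon pair, names `"A|B"` with `A < B`),
#'   `max_intra` (named vector) and `min_inter` (named vector).
#' @export
intra_inter_partition <- function(dm, taxon_map) {
  labels <- rownames(dm)
  tx <- .taxon_lookup(labels, taxon_map)
  taxa <- sort(unique(tx))
  intra <- stats::setNames(lapply(taxa, function(t) numeric(0)), taxa)
  inter <- list()
  n <- length(labels)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (tx[i] == tx[j]) {
        intra[[tx[i]]] <- c(intra[[tx[i]]], dm[i, j])
      } else {
        key <- paste(sort(c(tx[i], tx[j])), collapse = "|")
        inter[[key]] <- c(inter[[key]], dm[i, j])
      }
    }
  }
  list(intra = intra, inter = inter,
       max_intra = vapply(intra, function(v) if (length(v)) max(v) else NA_real_,
                          numeric(1)),
       min_inter = vapply(inter, min, numeric(1)))
}

#' Barcode-gap report over all taxon pairs
#'
#' For each unordered pair of taxa the gap is the smallest between-taxon
#' distance minus the larger of the two within-taxon maxima; a positive gap
#' means the barcode separates the pair. Pairs involving a singleton taxon
#' (no within-taxon distance) are reported with `NA` intra maxima and
#' flagged.
#'
#' @inheritParams intra_inter_partition
#' @return data frame with one row per taxon pair: `taxon_a`, `taxon_b`,
#'   `max_intra_a`, `max_intra_b`, `min_inter`, `gap`, `gap_present`,
#'   `singleton` flag; plus attribute `overall` with the global minimum gap.
#' @export
barcode_gap_report <- function(dm, taxon_map) {
  part <- intra_inter_partition(dm, taxon_map)
  taxa <- names(part$intra)
  labels <- rownames(dm)
  tx <- .taxon_lookup(labels, taxon_map)
  sizes <- table(tx)
  rows <- list()
  if (length(taxa) >= 2L) {
    for (i in seq_len(length(taxa) - 1L)) {
      for (j in (i + 1L):length(taxa)) {
        a <- taxa[i]; b <- taxa[j]
        key <- paste(sort(c(a, b)), collapse = "|")
        min_inter <- part$min_inter[key]
        ia <- part$max_intra[a]; ib <- part$max_intra[b]
        singleton <- sizes[a] < 2L || sizes[b] < 2L
        gap <- if (singleton) NA_real_ else min_inter - max(ia, ib)
        rows[[key]] <- data.frame(
          taxon_a = a, taxon_b = b,
          max_intra_a = unname(ia), max_intra_b = unname(ib),
          min_inter = unname(min_inter),
          gap = unname(gap),
          gap_present = if (singleton) NA else unname(gap) > 0,
          singleton = unname(singleton),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "overall") <- if (any(!out$singleton)) min(out$gap[!out$singleton]) else NA_real_
  out
}

#' Retain candidates within a percent-distance threshold of a query
#'
#' Each candidate is globally aligned to the query (match +1, mismatch -1,
#' linear gap -2 by default) and kept when the resulting percent difference
#' does not exceed `max_percent` -- the "not more than 5%" style of database
#' filtering used to assemble sequence sets around a type strain.
#'
#' @param query single-row `seq_records` (or a residue string).
#' @param candidates `seq_records` of candidates (unaligned).
#' @param max_percent retention threshold in percent.
#' @param policy ambiguity policy applied to the aligned pair
#'   (default `set-overlap`, appropriate when consensus records with
#'   ambiguity codes participate).
#' @return the retained subset of `candidates` (input order preserved), with
#'   a `percent` column of distances added.
#' @export
similarity_filter <- function(query, candidates, max_percent,
                              policy = c("set-overlap", "strict")) {
  policy <- .policy_match(match.arg(policy))
  qres <- if (is.data.frame(query)) query$residues[1] else query
  qres <- gsub("-", "", qres, fixed = TRUE)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                      baseOnly = FALSE)
  perc <- vapply(seq_len(nrow(candidates)), function(i) {
    cres <- gsub("-", "", candidates$residues[i], fixed = TRUE)
    al <- Biostrings::pairwiseAlignment(qres, cres, type = "global",
                                        substitutionMatrix = sub_mat,
                                        gapOpening = 0, gapExtension = 2)
    pa <- as.character(Biostrings::alignedPattern(al))
    sa <- as.character(Biostrings::alignedSubject(al))
    pairwise_distance(pa, sa, policy = policy)$percent
  }, numeric(1))
  keep <- perc <= max_percent
  out <- candidates[keep, , drop = FALSE]
  out$percent <- perc[keep]
  rownames(out) <- NULL
  out
}

#' Histogram of pairwise distances
#'
#' Left-closed, right-open bins starting at zero, the layout used to display
#' the distribution of intragenomic and interstrain barcode distances.
#'
#' @param values non-negative numeric values.
#' @param bin_width positive bin width.
#' @return data frame with `lower`, `upper`, `count` (empty input gives an
#'   empty data frame); counts sum to `length(values)`.
#' @export
distance_histogram <- function(values, bin_width) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    .rdnadiv_error("rdnadiv_bad_bin_width", "bin width must be a positive number")
  }
  if (any(values < 0)) {
    .rdnadiv_error("rdnadiv_negative_value", "distance values must be non-negative")
  }
  if (length(values) == 0L) {
    return(data.frame(lower = numeric(0), upper = numeric(0), count = integer(0)))
  }
  idx <- floor(values / bin_width)
  tab <- table(factor(idx, levels = 0:max(idx)))
  data.frame(lower = as.numeric(names(tab)) * bin_width,
             upper = (as.numeric(names(tab)) + 1) * bin_width,
             count = as.integer(tab))
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm matrix from [distance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  labs <- sprintf("%-10s", substr(rownames(dm), 1, 10))
  for (i in seq_len(nrow(dm))) {
    writeLines(paste0(labs[i], paste(sprintf("%.6f", dm[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}
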