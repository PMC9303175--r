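# Polymorphic IUPAC consensus barcodes and the in-silico Sanger consensus.
# A strain whose rDNA repeats are heterogeneous has no single "true" barcode
# sequence: the proposed representation is a consensus with di-, tri- or
# tetramorphic IUPAC symbols at the positions where repeat variants
# alternate. The Sanger emulation reproduces what a basecaller reports: a
# minor variant enters the called set only when its (abundance-weighted)
# proportion reaches the detection threshold.

# shared core: weighted per-column state proportions -> called sets
# returns list(consensus, proportions (5 x L: A C G T gap), arity, fallback)
.consensus_core <- function(m, weights, threshold, gap_majority = 0.5) {
  L <- ncol(m)
  bases <- c("A", "C", "G", "T")
  props <- matrix(0, 5, L, dimnames = list(c(bases, "-"), NULL))
  cons <- character(L)
  arity <- integer(L)
  fallback <- logical(L)
  w <- weights / sum(weights)
  for (col in seq_len(L)) {
    obs <- m[, col]
    gap_p <- sum(w[obs == "-"])
    keep <- obs %in% bases
    props["-", col] <- gap_p
    if (!any(keep)) { cons[col] <- "-"; next }
    pw <- tapply(w[keep], factor(obs[keep], levels = bases), sum)
    pw[is.na(pw)] <- 0
    pw_norm <- pw / sum(pw)   # proportions among non-gap states
    props[bases, col] <- pw_norm
    if (gap_p > gap_majority) { cons[col] <- "-"; arity[col] <- 0L; next }
    called <- bases[pw_norm >= threshold]
    if (length(called) == 0L) {
      called <- bases[which.max(pw_norm)]
      fallback[col] <- TRUE
    }
    arity[col] <- length(called)
    cons[col] <- iupac_symbol(called)
  }
  list(consensus = paste(cons, collapse = ""), proportions = props,
       arity = arity, fallback = fallback)
}

.aln_or_matrix <- function(aln) {
  if (inherits(aln, "barcode_alignment")) aln_matrix(aln) else aln
}

#' Polymorphic IUPAC consensus of an alignment
#'
#' Per column, the called state set contains every state whose proportion
#' (among non-gap residues) reaches `min_proportion`; the emitted symbol is
#' the IUPAC code of that set, so columns become mono-, di-, tri- or
#' tetramorphic. When no state reaches the threshold the majority state is
#' called and the column flagged. A column with gap proportion above 0.5 is
#' emitted as `-` to keep the consensus alignable.
#'
#' @param aln a `barcode_alignment` (or character matrix).
#' @param min_proportion calling threshold in (0, 1].
#' @param id id given to the consensus record.
#' @return a `consensus_result`: list with `record` (single-row
#'   `seq_records`, source `consensus`), `proportions` (5 x L matrix:
#'   A, C, G, T, gap), `arity`, `fallback` columns, `threshold`.
#' @export
iupac_consensus <- function(aln, min_proportion, id = "consensus") {
  m <- .aln_or_matrix(aln)
  if (nrow(m) == 0L) .rdnadiv_error("rdnadiv_empty_alignment", "empty alignment")
  if (!is.numeric(min_proportion) || min_proportion <= 0 || min_proportion > 1) {
    .rdnadiv_error("rdnadiv_bad_threshold", "min_proportion must be in (0, 1]")
  }
  core <- .consensus_core(m, rep(1, nrow(m)), min_proportion)
  rec <- seq_records(id = id, residues = core$consensus, source = "consensus")
  structure(list(record = rec, proportions = core$proportions,
                 arity = core$arity, fallback = core$fallback,
                 threshold = min_proportion),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result (threshold %g): %d columns, %d polymorphic\n",
              x$threshold, length(x$arity), sum(x$arity > 1)))
  invisible(x)
}

#' Majority-rule consensus of an alignment
#'
#' Per-column majority state; ties are resolved towards the first base in
#' the fixed order A < C < G < T and logged in the attribute `ties`
#' (1-based column indices).
#'
#' @param aln a `barcode_alignment` (or character matrix).
#' @param id id of the returned record.
#' @return single-row `seq_records` with source `consensus`.
#' @export
majority_consensus <- function(aln, id = "majority") {
  m <- .aln_or_matrix(aln)
  if (nrow(m) == 0L) .rdnadiv_error("rdnadiv_empty_alignment", "empty alignment")
  bases <- c("A", "C", "G", "T")
  ties <- integer(0)
  cons <- vapply(seq_len(ncol(m)), function(col) {
    obs <- m[, col]
    if (mean(obs == "-") > 0.5) return("-")
    obs <- obs[obs %in% bases]
    if (!length(obs)) return("-")
    tab <- table(factor(obs, levels = bases))
    top <- bases[tab == max(tab)]
    if (length(top) > 1L) ties <<- c(ties, col)
    top[1]
  }, "")
  rec <- seq_records(id = id, residues = paste(cons, collapse = ""),
                     source = "consensus")
  attr(rec, "ties") <- ties
  rec
}

#' In-silico Sanger consensus with a minor-variant detection threshold
#'
#' Emulates direct (uncloned) Sanger sequencing of a heterogeneous repeat
#' pool: per column the repeat states are weighted by repeat abundance, and
#' every state whose weighted proportion reaches `detect_threshold` enters
#' the called set, producing an IUPAC ambiguity symbol where variants
#' co-occur above the threshold. Intragenomic diversity below the threshold
#' remains invisible -- the mechanism by which divergent minor repeats stay
#' undetected in a strain's "taxonomic sequence".
#'
#' @param repeats a `barcode_alignment` (or character matrix) of repeat
#'   copies.
#' @param abundances repeat abundances summing to 1 (default uniform).
#' @param detect_threshold minor-variant detection threshold (default 0.25).
#' @param id id of the returned record.
#' @return a `consensus_result` whose `record` is the emulated Sanger read.
#' @export
sanger_emulation <- function(repeats, abundances = NULL,
                             detect_threshold = 0.25, id = "sanger") {
  m <- .aln_or_matrix(repeats)
  if (nrow(m) == 0L) .rdnadiv_error("rdnadiv_empty_alignment", "empty repeat set")
  if (is.null(abundances)) abundances <- rep(1 / nrow(m), nrow(m))
  if (length(abundances) != nrow(m)) {
    .rdnadiv_error("rdnadiv_abundance_mismatch",
                   "abundances and repeat count differ in length")
  }
  if (abs(sum(abundances) - 1) > 1e-8) {
    .rdnadiv_error("rdnadiv_abundance_mismatch", "abundances must sum to 1")
  }
  core <- .consensus_core(m, abundances, detect_threshold)
  rec <- seq_records(id = id, residues = core$consensus, source = "consensus")
  structure(list(record = rec, proportions = core$proportions,
                 arity = core$arity, fallback = core$fallback,
                 threshold = detect_threshold),
            class = "consensus_result")
}

#' Write per-column consensus proportions as TSV
#'
#' @param x a `consensus_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(x, path) {
  df <- data.frame(column = seq_along(x$arity),
                   symbol = strsplit(x$record$residues, "", fixed = TRUE)[[1]],
                   t(x$proportions), arity = x$arity, fallback = x$fallback)
  names(df)[3:7] <- c("A", "C", "G", "T", "gap")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
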