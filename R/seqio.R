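#' Expand an IUPAC symbol to its base set
#'
#' @param symbol a single IUPAC nucleotide symbol (DNA view; `U` is accepted
#'   and treated as `T`). The gap symbol `-` expands to the empty set.
#' @return character vector of unambiguous bases (`A`, `C`, `G`, `T`).
#' @examples
#' iupac_set("R")  # A, G
#' iupac_set("N")  # A, C, G, T
#' @export
iupac_set <- function(symbol) {
  stopifnot(length(symbol) == 1L, is.character(symbol))
  s <- chartr("u", "t", toupper(symbol))
  s <- chartr("U", "T", s)
  if (!s %in% .ALPHABET) {
    .rdnadiv_error("rdnadiv_unknown_symbol", sprintf("unknown IUPAC symbol '%s'", symbol))
  }
  .IUPAC[[s]]
}

#' IUPAC symbol for a set of bases
#'
#' Inverse of [iupac_set()]: maps a set of unambiguous bases to the single
#' IUPAC code that expands to exactly that set.
#'
#' @param bases character vector over `A`,`C`,`G`,`T` (empty set gives `-`).
#' @return single IUPAC symbol.
#' @export
iupac_symbol <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  sym <- .IUPAC_REV[key]
  if (is.na(sym)) {
    .rdnadiv_error("rdnadiv_unknown_symbol",
                   sprintf("no IUPAC symbol for base set {%s}", paste(bases, collapse = ",")))
  }
  unname(sym)
}

# Normalize residues: uppercase, U -> T; validate against the IUPAC alphabet.
# Typed error names the offending record and 1-based position.
.normalize_residues <- function(x, id = "?", allow_gaps = TRUE) {
  y <- chartr("u", "t", toupper(x))
  y <- chartr("U", "T", y)
  chars <- strsplit(y, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) {
    .rdnadiv_error("rdnadiv_empty_sequence", sprintf("record '%s' has no residues", id))
  }
  bad <- which(!chars %in% .ALPHABET)
  if (length(bad)) {
    .rdnadiv_error("rdnadiv_illegal_character",
                   sprintf("record '%s': illegal character '%s' at position %d",
                           id, chars[bad[1]], bad[1]))
  }
  if (!allow_gaps && any(chars == "-")) {
    .rdnadiv_error("rdnadiv_unexpected_gap",
                   sprintf("record '%s': gap character at position %d in unaligned input",
                           id, which(chars == "-")[1]))
  }
  y
}

#' Construct a set of sequence records
#'
#' The basic container used throughout the package: one row per sequence with
#' an id, an optional taxon label, a source tag and the residues (normalized
#' to uppercase DNA; `U` is mapped to `T` on input and can be restored on
#' output).
#'
#' @param id character vector of unique record ids.
#' @param residues character vector of sequences (IUPAC DNA, gaps allowed).
#' @param taxon taxon labels (recycled; may be empty strings).
#' @param source one of `clone`, `genome`, `database`, `consensus`,
#'   `simulated` (recycled).
#' @param allow_gaps if `FALSE`, a gap character is an error (unaligned input).
#' @return a `seq_records` data frame with columns `id`, `taxon`, `source`,
#'   `residues`.
#' @export
seq_records <- function(id, residues, taxon = "", source = "clone",
                        allow_gaps = TRUE) {
  stopifnot(length(id) == length(residues))
  if (anyDuplicated(id)) {
    .rdnadiv_error("rdnadiv_duplicate_id",
                   sprintf("duplicate record id '%s'", id[duplicated(id)][1]))
  }
  source <- match.arg(source, c("clone", "genome", "database", "consensus", "simulated"),
                      several.ok = FALSE)
  residues <- vapply(seq_along(residues), function(i) {
    .normalize_residues(residues[i], id = id[i], allow_gaps = allow_gaps)
  }, "")
  out <- data.frame(id = as.character(id),
                    taxon = rep_len(as.character(taxon), length(id)),
                    source = rep_len(source, length(id)),
                    residues = residues,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @param taxon_from how to derive the taxon label from the header: `"pipe"`
#'   (default; the token after the last `|`, empty if no `|`), `"none"`, or
#'   `"map"` (look ids up in `taxon_map`).
#' @param taxon_map optional two-column data frame (`id`, `taxon`) or a path
#'   to a two-column tab-separated file, used when `taxon_from = "map"`.
#' @param allow_gaps whether `-` characters are legal (aligned FASTA).
#' @param source source tag recorded on every record.
#' @return a `seq_records` data frame.
#' @export
read_fasta <- function(path, taxon_from = c("pipe", "none", "map"),
                       taxon_map = NULL, allow_gaps = TRUE, source = "clone") {
  taxon_from <- match.arg(taxon_from)
  if (!file.exists(path)) {
    .rdnadiv_error("rdnadiv_io_error", sprintf("no such file: %s", path))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .rdnadiv_error("rdnadiv_io_error",
                    sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L) {
    .rdnadiv_error("rdnadiv_empty_file", sprintf("FASTA file '%s' contains no records", path))
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  taxa <- rep("", length(ids))
  if (taxon_from == "pipe") {
    has_pipe <- grepl("|", ids, fixed = TRUE)
    taxa[has_pipe] <- vapply(strsplit(ids[has_pipe], "|", fixed = TRUE),
                             function(x) x[length(x)], "")
  } else if (taxon_from == "map") {
    if (is.character(taxon_map) && length(taxon_map) == 1L) {
      taxon_map <- read_taxon_map(taxon_map)
    }
    stopifnot(is.data.frame(taxon_map))
    m <- match(ids, taxon_map[[1]])
    taxa <- ifelse(is.na(m), "", as.character(taxon_map[[2]][m]))
  }
  seq_records(id = ids, residues = as.character(set), taxon = taxa,
              source = source, allow_gaps = allow_gaps)
}

#' Write sequence records to FASTA
#'
#' Round-trips with [read_fasta()]: ids and residues are reproduced
#' byte-identically (taxon labels are not re-embedded in headers).
#'
#' @param records a `seq_records` data frame.
#' @param path output path.
#' @param rna if `TRUE`, residues are written in the RNA view (`T` -> `U`).
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, rna = FALSE, width = 70L) {
  res <- records$residues
  if (rna) res <- chartr("T", "U", res)
  set <- Biostrings::BStringSet(res)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a two-column id-to-taxon mapping file
#'
#' @param path tab-separated file with columns id and taxon (no header, or a
#'   header line starting with `id`).
#' @return data frame with columns `id` and `taxon`.
#' @export
read_taxon_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) {
    .rdnadiv_error("rdnadiv_io_error", "taxon map must have two tab-separated columns")
  }
  if (identical(tolower(tab[1, 1]), "id")) tab <- tab[-1, , drop = FALSE]
  out <- data.frame(id = as.character(tab[[1]]), taxon = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count ambiguous positions in a sequence
#'
#' The number of positions whose symbol is not in `A`,`C`,`G`,`T`,`-` -- the
#' ambiguity load that a Sanger consensus read accumulates when divergent
#' repeat variants co-amplify above the basecaller's detection threshold.
#'
#' @param x a `seq_records` data frame, or a character vector of residues.
#' @return integer vector of counts (one per record).
#' @export
count_ambiguous_positions <- function(x) {
  res <- if (is.data.frame(x)) x$residues else x
  vapply(res, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(!chars %in% .UNAMBIGUOUS)
  }, integer(1), USE.NAMES = FALSE)
}

#' Construct an alignment from equal-length records
#'
#' @param records a `seq_records` data frame whose residues all have the same
#'   length.
#' @param regions optional data frame of sub-segment annotations with columns
#'   `name`, `start`, `end` (1-based inclusive alignment columns), e.g.
#'   ITS1 / 5.8S / ITS2. Intervals must be in range and non-overlapping.
#' @return a `barcode_alignment` object (list with `records`, `length`,
#'   `regions`).
#' @export
alignment <- function(records, regions = NULL) {
  stopifnot(inherits(records, "data.frame"), nrow(records) >= 1L)
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1L) {
    .rdnadiv_error("rdnadiv_length_mismatch",
                   sprintf("alignment rows differ in length (%s)",
                           paste(unique(lens), collapse = ", ")))
  }
  L <- lens[1]
  if (!is.null(regions)) {
    stopifnot(all(c("name", "start", "end") %in% names(regions)))
    if (any(regions$start < 1L) || any(regions$end > L) ||
        any(regions$start > regions$end)) {
      .rdnadiv_error("rdnadiv_bad_region", "region interval outside alignment bounds")
    }
    o <- order(regions$start)
    r <- regions[o, ]
    if (nrow(r) > 1L && any(r$start[-1] <= r$end[-nrow(r)])) {
      .rdnadiv_error("rdnadiv_bad_region", "region intervals overlap")
    }
  }
  structure(list(records = records, length = L, regions = regions),
            class = "barcode_alignment")
}

# alignment -> character matrix (rows = records, named)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$records$residues, "", fixed = TRUE))
  rownames(m) <- aln$records$id
  m
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("barcode_alignment: %d sequences x %d columns\n",
              nrow(x$records), x$length))
  if (!is.null(x$regions)) {
    cat("regions:", paste(sprintf("%s[%d-%d]", x$regions$name, x$regions$start,
                                  x$regions$end), collapse = ", "), "\n")
  }
  invisible(x)
}

# reverse complement on plain character strings, IUPAC-aware
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
         "", USE.NAMES = FALSE)
}
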