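# Variable-site detection and secondary-structure-aware classification.
# Variable alignment columns are read against a base-pairing map of the
# reference transcript: substitutions at unpaired (loop) positions are
# structurally neutral, substitutions in stems are tolerated when wobble
# (G.U) pairing or a compensatory change on the partner strand preserves the
# helix, and non-canonical combinations are evidence that the repeat copy is
# a pseudogene.

.CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

.to_rna <- function(x) chartr("T", "U", x)

#' Parse a dot-bracket secondary structure
#'
#' @param seq reference sequence (DNA or RNA view; stored as RNA).
#' @param structure dot-bracket string of the same length. Bracket tiers
#'   `()`, `[]` and `{}` are supported; `.` (and `,`/`:`) mark unpaired
#'   positions.
#' @param loops optional data frame of loop/domain annotations (`name`,
#'   `start`, `end`, 1-based inclusive reference coordinates).
#' @param cbc_pairs optional two-column matrix/data.frame of reference
#'   position pairs designated as undergoing concerted compensatory change.
#' @param pseudoknot_free if `TRUE`, crossing pairs (pseudoknots across
#'   bracket tiers) are an error.
#' @return a `secondary_structure` object: list with `reference` (RNA),
#'   `pairs` (two-column matrix, i < j, 1-based), `partner` (integer vector,
#'   `NA` where unpaired), `loops`, `cbc_pairs`.
#' @export
parse_dotbracket <- function(seq, structure, loops = NULL, cbc_pairs = NULL,
                             pseudoknot_free = FALSE) {
  if (nchar(seq) != nchar(structure)) {
    .rdnadiv_error("rdnadiv_length_mismatch",
                   "sequence and structure strings differ in length")
  }
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  tiers <- list(c("(", ")"), c("[", "]"), c("{", "}"))
  unpaired_ok <- c(".", ",", ":", "-")
  pairs <- matrix(integer(0), ncol = 2)
  for (tier in tiers) {
    stack <- integer(0)
    for (i in seq_along(chars)) {
      if (chars[i] == tier[1]) {
        stack <- c(stack, i)
      } else if (chars[i] == tier[2]) {
        if (length(stack) == 0L) {
          .rdnadiv_error("rdnadiv_unbalanced_structure",
                         sprintf("unmatched '%s' at position %d", tier[2], i))
        }
        pairs <- rbind(pairs, c(stack[length(stack)], i))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) {
      .rdnadiv_error("rdnadiv_unbalanced_structure",
                     sprintf("unmatched '%s' at position %d", tier[1],
                             stack[length(stack)]))
    }
  }
  bad <- !chars %in% c(unlist(tiers), unpaired_ok)
  if (any(bad)) {
    .rdnadiv_error("rdnadiv_bad_structure_char",
                   sprintf("illegal structure character '%s' at position %d",
                           chars[which(bad)[1]], which(bad)[1]))
  }
  partner <- rep(NA_integer_, length(chars))
  if (nrow(pairs)) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
    if (pseudoknot_free && nrow(pairs) > 1L) {
      o <- order(pairs[, 1])
      p <- pairs[o, , drop = FALSE]
      for (a in seq_len(nrow(p) - 1L)) {
        crossing <- p[-seq_len(a), 1] < p[a, 2] & p[-seq_len(a), 2] > p[a, 2]
        if (any(crossing)) {
          .rdnadiv_error("rdnadiv_pseudoknot", "crossing base pairs present")
        }
      }
    }
  }
  if (!is.null(cbc_pairs)) {
    cbc_pairs <- as.matrix(cbc_pairs)[, 1:2, drop = FALSE]
    storage.mode(cbc_pairs) <- "integer"
    # normalize to i < j
    cbc_pairs <- t(apply(cbc_pairs, 1, sort))
  }
  structure(list(reference = .to_rna(toupper(seq)),
                 pairs = pairs, partner = partner,
                 loops = loops, cbc_pairs = cbc_pairs),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary_structure: %d nt, %d base pairs\n",
              nchar(x$reference), nrow(x$pairs)))
  invisible(x)
}

# map alignment columns to reference coordinates (NA where ref row has a gap)
.ref_coords <- function(ref_row) {
  nongap <- ref_row != "-"
  coords <- rep(NA_integer_, length(ref_row))
  coords[nongap] <- seq_len(sum(nongap))
  coords
}

# substitution class from an observed state set (RNA letters)
.subst_class <- function(states) {
  s <- sort(states)
  if (length(s) > 2L) return("mixed")
  key <- paste(s, collapse = "")
  if (key == "CU") return("pyrimidine transition")
  if (key == "AG") return("purine transition")
  "transversion"
}

#' Detect variable alignment columns
#'
#' A column is variable when at least two states occur among the (ungapped)
#' sequences and the total count of non-majority states reaches
#' `min_minor_count`. The default of 3 excludes singleton and doubleton
#' substitutions, which in cloned amplicon sets are mostly amplification
#' (Taq) errors. Dimorphic columns -- exactly two alternating states -- are
#' the classical SND (single-nucleotide dimorphism) sites.
#'
#' @param aln a `barcode_alignment`; states are read in the RNA view.
#' @param structure optional `secondary_structure` defined on the reference
#'   row; provides the pairing context.
#' @param min_minor_count minimum total minor-state count (default 3).
#' @param ref reference row (id or index, default first row) used to anchor
#'   alignment columns to structure coordinates. Columns where the reference
#'   has a gap are reported but structurally unanchored.
#' @return data frame of class `variable_sites`: one row per variable
#'   column with alignment column, reference column, observed states and
#'   counts, arity, substitution class, pairing context, partner column and
#'   pairing-effect class. The full per-site state vectors are kept in the
#'   attribute `state_rows` for downstream per-sequence analysis.
#' @export
find_variable_sites <- function(aln, structure = NULL, min_minor_count = 3L,
                                ref = 1L) {
  m <- aln_matrix(aln)
  if (nrow(m) == 0L) .rdnadiv_error("rdnadiv_empty_alignment", "empty alignment")
  m <- matrix(.to_rna(m), nrow = nrow(m), dimnames = dimnames(m))
  if (is.character(ref)) ref <- match(ref, rownames(m))
  coords <- .ref_coords(m[ref, ])
  partner_ref <- if (!is.null(structure)) structure$partner else NULL
  # reference coordinate -> alignment column
  aln_col_of_ref <- match(seq_len(max(coords, na.rm = TRUE)), coords)

  rows <- list()
  state_rows <- list()
  for (col in seq_len(ncol(m))) {
    obs <- m[, col]
    counted <- obs[obs %in% c("A", "C", "G", "U")]
    if (length(counted) == 0L) next
    tab <- sort(table(counted), decreasing = TRUE)
    if (length(tab) < 2L) next
    minor <- sum(tab) - tab[1]
    if (minor < min_minor_count) next
    states <- names(tab)
    rc <- coords[col]
    context <- "unanchored"
    partner_col <- NA_integer_
    partner_aln <- NA_integer_
    if (!is.na(rc)) {
      context <- "unpaired"
      if (!is.null(partner_ref) && !is.na(partner_ref[rc])) {
        context <- "paired"
        partner_col <- partner_ref[rc]
        partner_aln <- aln_col_of_ref[partner_col]
      }
    }
    effect <- "neutral_unpaired"
    subtype <- NA_character_
    if (context == "paired" && !is.na(partner_aln)) {
      cl <- classify_pairing_effect(obs, m[, partner_aln])
      effect <- cl$effect
      subtype <- cl$subtype
    } else if (context == "unanchored") {
      effect <- NA_character_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      column = col, ref_column = rc,
      states = paste(states, collapse = "/"),
      counts = paste(as.integer(tab), collapse = "/"),
      n_states = length(tab),
      arity = c("monomorphic", "dimorphic", "trimorphic", "tetramorphic")[length(tab)],
      minor_count = as.integer(minor),
      subst_class = .subst_class(states),
      context = context,
      partner_column = partner_col,
      partner_aln_column = partner_aln,
      pairing_effect = effect,
      subtype = subtype,
      stringsAsFactors = FALSE)
    state_rows[[as.character(col)]] <- obs
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = integer(0), ref_column = integer(0), states = character(0),
               counts = character(0), n_states = integer(0), arity = character(0),
               minor_count = integer(0), subst_class = character(0),
               context = character(0), partner_column = integer(0),
               partner_aln_column = integer(0), pairing_effect = character(0),
               subtype = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "state_rows") <- state_rows
  attr(out, "min_minor_count") <- min_minor_count
  class(out) <- c("variable_sites", "data.frame")
  out
}

#' Classify the structural effect of variation at a paired site
#'
#' The per-sequence (row-wise) combinations of (site state, partner state)
#' are examined, not the column marginals; this distinguishes a concerted
#' compensatory base change (CBC) from coincidental variability on both
#' strands, and identifies the individual sequences that carry broken pairs.
#'
#' * `mismatch` -- some sequence carries a non-canonical combination.
#' * `wobble_neutral` -- only one column varies and every observed state
#'   still pairs canonically (including G.U wobble) with the invariant
#'   partner; such single-side canonical-preserving changes are hemi-CBCs,
#'   reported in `subtype`.
#' * `CBC` -- both columns vary, every observed combination is canonical,
#'   and the combinations differ between sequence groups.
#'
#' @param site_states,partner_states character vectors of per-sequence
#'   states at the two columns (RNA or DNA letters; gaps/ambiguity ignored).
#' @param canonical canonical pair set (default Watson-Crick + wobble).
#' @return list with `effect`, `subtype`, `combos` (observed combinations)
#'   and `noncanonical` (logical per sequence, `NA` where not assessable).
#' @export
classify_pairing_effect <- function(site_states, partner_states,
                                    canonical = .CANONICAL_PAIRS) {
  if (length(site_states) != length(partner_states)) {
    .rdnadiv_error("rdnadiv_length_mismatch", "state vectors differ in length")
  }
  s <- .to_rna(toupper(site_states))
  p <- .to_rna(toupper(partner_states))
  ok <- s %in% c("A", "C", "G", "U") & p %in% c("A", "C", "G", "U")
  if (!any(ok)) {
    .rdnadiv_error("rdnadiv_missing_partner", "no assessable (site, partner) combinations")
  }
  combo <- paste0(s, p)
  noncanon <- ifelse(ok, !combo %in% canonical, NA)
  combos <- unique(combo[ok])
  site_var <- length(unique(s[ok])) > 1L
  partner_var <- length(unique(p[ok])) > 1L
  if (any(noncanon[ok])) {
    effect <- "mismatch"; subtype <- NA_character_
  } else if (site_var && partner_var && length(combos) > 1L) {
    effect <- "CBC"; subtype <- NA_character_
  } else if (site_var || partner_var) {
    effect <- "wobble_neutral"; subtype <- "hemi_CBC"
  } else {
    effect <- "wobble_neutral"; subtype <- NA_character_
  }
  list(effect = effect, subtype = subtype, combos = combos,
       noncanonical = noncanon)
}

#' Flag putative pseudogene sequences from broken designated pairs
#'
#' A sequence is flagged when it carries at least one non-canonical
#' combination at a CBC-designated pair: a pair classified `CBC` among the
#' variable sites, or a pair listed in `structure$cbc_pairs`. Mismatches at
#' other stem pairs are reported among the variable sites but are not by
#' themselves pseudogene evidence, mirroring the argument that it is the
#' concerted compensatory positions whose disruption marks an inactive
#' repeat. Each flag cites the offending column pair and the carried
#' combination.
#'
#' @param aln a `barcode_alignment`.
#' @param structure `secondary_structure` anchored on the reference row.
#' @param sites result of [find_variable_sites()] on the same alignment.
#' @param ref reference row (id or index) used for coordinate anchoring.
#' @return a `site_classification_report`: list with `sites`, `flags`
#'   (data frame id / flagged / reasons), and `region_variability`
#'   (variable columns / region length per annotated region).
#' @export
flag_pseudogenes <- function(aln, structure, sites, ref = 1L) {
  m <- aln_matrix(aln)
  m <- matrix(.to_rna(m), nrow = nrow(m), dimnames = dimnames(m))
  if (is.character(ref)) ref <- match(ref, rownames(m))
  coords <- .ref_coords(m[ref, ])
  aln_col_of_ref <- match(seq_len(max(coords, na.rm = TRUE)), coords)

  # designated pairs in reference coordinates
  designated <- matrix(integer(0), ncol = 2)
  cbc_sites <- sites[!is.na(sites$pairing_effect) &
                       sites$pairing_effect == "CBC" &
                       !is.na(sites$partner_column), , drop = FALSE]
  if (nrow(cbc_sites)) {
    designated <- rbind(designated,
                        t(apply(cbind(cbc_sites$ref_column,
                                      cbc_sites$partner_column), 1, sort)))
  }
  if (!is.null(structure$cbc_pairs) && nrow(structure$cbc_pairs)) {
    designated <- rbind(designated, structure$cbc_pairs)
  }
  designated <- unique(designated)

  ids <- rownames(m)
  flagged <- rep(FALSE, length(ids))
  reasons <- rep("", length(ids))
  if (nrow(designated)) {
    for (k in seq_len(nrow(designated))) {
      i <- designated[k, 1]; j <- designated[k, 2]
      ci <- aln_col_of_ref[i]; cj <- aln_col_of_ref[j]
      if (is.na(ci) || is.na(cj)) next
      s <- m[, ci]; p <- m[, cj]
      ok <- s %in% c("A", "C", "G", "U") & p %in% c("A", "C", "G", "U")
      bad <- ok & !paste0(s, p) %in% .CANONICAL_PAIRS
      if (any(bad)) {
        flagged[bad] <- TRUE
        r <- sprintf("pair %d-%d carries %s", i, j, paste0(s[bad], "-", p[bad]))
        reasons[bad] <- ifelse(reasons[bad] == "", r,
                               paste(reasons[bad], r, sep = "; "))
      }
    }
  }
  flags <- data.frame(id = ids, flagged = flagged, reasons = reasons,
                      stringsAsFactors = FALSE)
  region_var <- NULL
  if (!is.null(aln$regions)) {
    region_var <- do.call(rbind, lapply(seq_len(nrow(aln$regions)), function(r) {
      reg <- aln$regions[r, ]
      nvar <- sum(sites$column >= reg$start & sites$column <= reg$end)
      data.frame(name = reg$name, length = reg$end - reg$start + 1L,
                 variable_columns = nvar,
                 fraction = nvar / (reg$end - reg$start + 1L),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(sites = sites, flags = flags, region_variability = region_var,
                 designated_pairs = designated),
            class = "site_classification_report")
}

#' @export
print.site_classification_report <- function(x, ...) {
  cat(sprintf("site_classification_report: %d variable sites, %d/%d sequences flagged\n",
              nrow(x$sites), sum(x$flags$flagged), nrow(x$flags)))
  invisible(x)
}

#' Write a variable-site report as TSV
#'
#' Coordinates are emitted 1-based inclusive.
#'
#' @param sites a `variable_sites` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a secondary structure as a Vienna dot-bracket file
#'
#' Three lines: a `>` header, the reference sequence (RNA view) and the
#' dot-bracket string; designated CBC pairs are appended as `# cbc i j`
#' comment lines.
#'
#' @param structure a `secondary_structure`.
#' @param path output path.
#' @param name header name.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(structure, path, name = "reference") {
  db <- rep(".", nchar(structure$reference))
  if (nrow(structure$pairs)) {
    db[structure$pairs[, 1]] <- "("
    db[structure$pairs[, 2]] <- ")"
  }
  lines <- c(paste0(">", name), structure$reference, paste(db, collapse = ""))
  if (!is.null(structure$cbc_pairs) && nrow(structure$cbc_pairs)) {
    lines <- c(lines, sprintf("# cbc %d %d", structure$cbc_pairs[, 1],
                              structure$cbc_pairs[, 2]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Vienna dot-bracket structure file
#'
#' @param path file written by [write_dotbracket()] (or any
#'   header/sequence/structure triple).
#' @return a `secondary_structure`.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1], ">")) {
    .rdnadiv_error("rdnadiv_io_error", "expected >name, sequence, structure lines")
  }
  cbc <- NULL
  cbc_lines <- grep("^# cbc ", lines, value = TRUE)
  if (length(cbc_lines)) {
    cbc <- do.call(rbind, lapply(strsplit(cbc_lines, "\\s+"), function(x)
      as.integer(x[3:4])))
  }
  parse_dotbracket(lines[2], lines[3], cbc_pairs = cbc)
}
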