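# Distance-based phylogenetics and reticulation diagnostics: neighbour
# joining with a documented deterministic tie-break, neighbour-net circular
# split systems with non-negative least-squares split weights, and quartet
# treelikeness statistics (delta score, Q-residual). A tree metric has delta
# score 0; reticulate (admixed) data push it towards 1.

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken deterministically towards the smallest (row, column) index pair in
#' the current matrix order. Negative branch lengths are clamped to zero;
#' the number of clamped branches is recorded in the attribute `clamped`.
#'
#' @param dm symmetric distance matrix with labels (n >= 3).
#' @return an [ape::read.tree()] `phylo` object (unrooted).
#' @export
nj_tree <- function(dm) {
  n <- nrow(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  if (n < 3L) .rdnadiv_error("rdnadiv_too_few_taxa", "neighbour joining needs n >= 3")
  D <- dm
  nodes <- rownames(dm)           # newick fragments
  clamped <- 0L
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest Q; ties -> lexicographically smallest (i, j), i < j
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; lj <- 0 }
    newnode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nodes <- c(nodes[keep], newnode)
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], "joined")
    D <- D2
  }
  # resolve the final three nodes around a central vertex
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- c(l1, l2, l3)
  clamped <- clamped + sum(ls < 0)
  ls[ls < 0] <- 0
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(ls[1]),
                 nodes[2], fmt(ls[2]), nodes[3], fmt(ls[3]))
  tree <- ape::read.tree(text = txt)
  if (clamped > 0L) {
    warning(sprintf("%d negative branch length(s) clamped to 0", clamped))
  }
  attr(tree, "clamped") <- clamped
  tree
}

#' Split system (bipartitions + branch lengths) of a phylogenetic tree
#'
#' Each edge of an unrooted tree induces one split; used to compare
#' neighbour-net output with tree topologies.
#'
#' @param tree a `phylo` object with edge lengths.
#' @param taxa taxon order for the membership matrix columns (default tip
#'   labels).
#' @return list with `membership` (logical splits x taxa, the side not
#'   containing the first taxon) and `weights` (edge lengths).
#' @export
tree_splits <- function(tree, taxa = tree$tip.label) {
  n <- length(tree$tip.label)
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  M <- matrix(FALSE, nrow(tree$edge), length(taxa),
              dimnames = list(NULL, taxa))
  for (e in seq_len(nrow(tree$edge))) {
    M[e, tree$tip.label[desc[[tree$edge[e, 2]]]]] <- TRUE
  }
  w <- tree$edge.length
  flip <- M[, 1]
  M[flip, ] <- !M[flip, , drop = FALSE]
  keep <- rowSums(M) > 0 & rowSums(M) < length(taxa)
  list(membership = M[keep, , drop = FALSE], weights = w[keep])
}

# all splits compatible with a circular ordering: arcs not containing the
# first cycle element; n(n-1)/2 of them
.circular_splits <- function(cycle) {
  n <- length(cycle)
  memb <- list()
  for (i in 2:n) for (j in i:n) {
    v <- rep(FALSE, n); names(v) <- cycle
    v[cycle[i:j]] <- TRUE
    memb[[length(memb) + 1L]] <- v
  }
  M <- do.call(rbind, memb)
  colnames(M) <- cycle
  M
}

#' Estimate non-negative split weights by least squares
#'
#' Fits the split metrics of a candidate split set to a distance matrix with
#' non-negative least squares (active-set method). The design has one column
#' per split and one row per taxon pair; entry 1 when the split separates
#' the pair.
#'
#' @param dm distance matrix.
#' @param membership logical matrix (splits x taxa) giving one side of each
#'   split; duplicate splits are rejected.
#' @return list with `weights` (>= 0) and `residual_norm`.
#' @export
estimate_split_weights <- function(dm, membership) {
  taxa <- colnames(membership)
  stopifnot(all(taxa %in% rownames(dm)))
  keys <- apply(membership, 1, function(v) paste(as.integer(v), collapse = ""))
  if (anyDuplicated(keys)) {
    .rdnadiv_error("rdnadiv_duplicate_split", "duplicate splits in candidate set")
  }
  n <- length(taxa)
  prs <- utils::combn(n, 2)
  X <- matrix(0, ncol(prs), nrow(membership))
  d <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    X[k, ] <- as.numeric(membership[, i] != membership[, j])
    d[k] <- dm[taxa[i], taxa[j]]
  }
  fit <- pracma::lsqnonneg(X, d)
  list(weights = as.numeric(fit$x),
       residual_norm = sqrt(sum((X %*% fit$x - d)^2)))
}

#' Neighbour-net circular split system
#'
#' Computes the neighbour-net circular ordering of the taxa (Bryant-Moulton
#' two-stage agglomeration), enumerates all `n(n-1)/2` splits compatible
#' with that ordering, and estimates their weights by non-negative least
#' squares. Splits with weight below `threshold` are dropped. On additive
#' (tree-metric) input the surviving splits are exactly the tree's splits
#' with weights equal to branch lengths; conflicting signal (reticulation)
#' shows up as incompatible splits with positive weight, the parallel-edge
#' "boxes" of a splits graph.
#'
#' @param dm symmetric labelled distance matrix, n >= 4 (for n < 4 the NJ
#'   tree's split system is returned).
#' @param threshold minimum reported split weight (default `1e-9`).
#' @return a `split_system`: list with `taxa` (input order), `cycle`
#'   (circular ordering), `membership` (logical splits x taxa matrix),
#'   `weights`, `residual_norm`, `threshold`.
#' @export
neighbour_net <- function(dm, threshold = 1e-9) {
  taxa <- rownames(dm)
  n <- length(taxa)
  if (n < 4L) {
    tree <- nj_tree(dm)
    ts <- tree_splits(tree, taxa)
    # collapse duplicate bipartitions (n=3: three leaf edges)
    return(structure(list(taxa = taxa, cycle = taxa,
                          membership = ts$membership, weights = ts$weights,
                          residual_norm = 0, threshold = threshold),
                     class = "split_system"))
  }
  nn <- phangorn::neighborNet(dm)
  sp <- nn$splits
  cycle <- attr(sp, "labels")[attr(sp, "cycle")]
  memb <- .circular_splits(cycle)
  memb <- memb[, taxa, drop = FALSE]  # report in input taxon order
  est <- estimate_split_weights(dm, memb)
  keep <- est$weights >= threshold
  structure(list(taxa = taxa, cycle = cycle,
                 membership = memb[keep, , drop = FALSE],
                 weights = est$weights[keep],
                 residual_norm = est$residual_norm,
                 threshold = threshold),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("split_system: %d taxa, %d splits (threshold %g), residual %.3g\n",
              length(x$taxa), nrow(x$membership), x$threshold, x$residual_norm))
  invisible(x)
}

#' Canonical string keys for a set of splits
#'
#' Each split is written as the sorted, comma-joined taxon side not
#' containing the first taxon; useful for comparing split sets.
#'
#' @param membership logical splits x taxa matrix.
#' @return character vector of keys.
#' @export
split_keys <- function(membership) {
  apply(membership, 1, function(v) {
    side <- colnames(membership)[v]
    other <- colnames(membership)[!v]
    a <- if (colnames(membership)[1] %in% side) other else side
    paste(sort(a), collapse = ",")
  })
}

#' Quartet delta score and Q-residual of a distance matrix
#'
#' For each quartet the three pairwise-sum values are ordered
#' `s1 >= s2 >= s3`; the quartet's delta is `(s1 - s2) / (s1 - s3)` (zero
#' when `s1 = s3`). An additive (tree) metric satisfies the four-point
#' condition `s1 = s2`, so its mean delta is 0; a fully conflicting
#' "box" quartet scores 1. The Q-residual is the mean of
#' `((s1 - s2) / scale)^2` with `scale` the mean off-diagonal distance.
#'
#' @param dm symmetric labelled distance matrix, n >= 4.
#' @return a `treelikeness_stats` list: `mean_delta`, `per_taxon_delta`
#'   (named vector), `q_residual`, `n_quartets`.
#' @export
delta_score <- function(dm) {
  n <- nrow(dm)
  if (n < 4L) .rdnadiv_error("rdnadiv_too_few_taxa", "delta score needs n >= 4")
  q <- utils::combn(n, 4)
  i <- q[1, ]; j <- q[2, ]; k <- q[3, ]; l <- q[4, ]
  s_a <- dm[cbind(i, j)] + dm[cbind(k, l)]
  s_b <- dm[cbind(i, k)] + dm[cbind(j, l)]
  s_c <- dm[cbind(i, l)] + dm[cbind(j, k)]
  s1 <- pmax(s_a, s_b, s_c)
  s3 <- pmin(s_a, s_b, s_c)
  s2 <- s_a + s_b + s_c - s1 - s3
  span <- s1 - s3
  delta <- ifelse(span <= .Machine$double.eps * pmax(1, s1), 0,
                  (s1 - s2) / span)
  scale <- mean(dm[upper.tri(dm)])
  qres <- if (scale > 0) mean(((s1 - s2) / scale)^2) else 0
  per_taxon <- vapply(seq_len(n), function(t) {
    mean(delta[i == t | j == t | k == t | l == t])
  }, numeric(1))
  names(per_taxon) <- rownames(dm)
  structure(list(mean_delta = mean(delta), per_taxon_delta = per_taxon,
                 q_residual = qres, n_quartets = ncol(q)),
            class = "treelikeness_stats")
}

#' @export
print.treelikeness_stats <- function(x, ...) {
  cat(sprintf("mean delta score %.4f over %d quartets; Q-residual %.4g\n",
              x$mean_delta, x$n_quartets, x$q_residual))
  invisible(x)
}

#' Write a split system as a NEXUS splits block
#'
#' The output is readable by standard split-network viewers (SplitsTree
#' dialect).
#'
#' @param ss a `split_system`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_splits_nexus <- function(ss, path) {
  con <- file(path, "w")
  on.exit(close(con))
  taxa <- ss$taxa
  n <- length(taxa)
  writeLines("#NEXUS", con)
  writeLines(sprintf("BEGIN Taxa;\nDIMENSIONS ntax=%d;\nTAXLABELS", n), con)
  writeLines(sprintf("  [%d] '%s'", seq_len(n), taxa), con)
  writeLines(";\nEND;", con)
  writeLines(sprintf("BEGIN Splits;\nDIMENSIONS ntax=%d nsplits=%d;", n,
                     nrow(ss$membership)), con)
  writeLines("FORMAT labels=no weights=yes confidences=no intervals=no;", con)
  cyc <- match(ss$cycle, taxa)
  writeLines(sprintf("CYCLE %s;", paste(cyc, collapse = " ")), con)
  writeLines("MATRIX", con)
  for (s in seq_len(nrow(ss$membership))) {
    idx <- which(ss$membership[s, ])
    writeLines(sprintf("[%d]\t%.10g\t%s,", s, ss$weights[s],
                       paste(idx, collapse = " ")), con)
  }
  writeLines(";\nEND;", con)
  invisible(path)
}

#' Write a split-system TSV (one split per row)
#'
#' @param ss a `split_system`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_splits_tsv <- function(ss, path) {
  df <- data.frame(split = split_keys(ss$membership), weight = ss$weights,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
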