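# Forward simulator of multicopy rDNA and single-copy gene evolution under
# three regimes: concerted homogenization (gene conversion within tandem
# arrays), birth-and-death turnover (duplication, loss, truncation /
# pseudogenization of dispersed repeats), and hybridization followed by
# mosaic (block-wise) genome reduction. It produces every input the rest of
# the pipeline consumes -- genomes, cloned repeat sequences, emulated Sanger
# consensus reads, structures, taxon maps -- together with ground-truth
# labels (repeat origin lineage, functional status, coordinates).

.DNA_CANONICAL <- c("AT", "TA", "GC", "CG", "GT", "TG")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulation configuration with study-scale defaults
#'
#' Defaults emulate a clade of six strains with a two-hairpin barcode unit
#' of 300 nt, around a dozen dispersed rDNA repeats per genome, a
#' transition-biased (kappa = 4) substitution process whose acceptance in
#' stems depends on the structural consequence (wobble-compatible changes
#' mostly tolerated, compensatory-pair-initiating changes intermediate,
#' mismatches rarely fixed), birth-and-death turnover, and no
#' homogenization across dispersed repeats. Hybridization events are off by
#' default and can be added as `list(list(parents = c("st1", "st3"), time =
#' 0.55, retention = 0.5))`.
#'
#' @param ... overrides of the default fields (unknown names are an error).
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    seed = 1L,
    tree = "((st1:0.5,st2:0.5):0.3,(st3:0.5,st4:0.5):0.3,(st5:0.6,st6:0.6):0.2);",
    repeat_length = 300L,
    n_repeats = 12L,
    mutation_rate = 0.03,      # substitutions proposed / site / time unit
    kappa = 4,                 # transition:transversion ratio
    wobble_accept = 0.8,       # canonical (incl. G.U) outcome in a stem
    cbc_accept = 0.4,          # non-canonical outcome at a designated CBC pair
    mismatch_accept = 0.05,    # non-canonical outcome elsewhere in a stem
    homogenization_rate = 0.5, # gene conversions / repeat / unit (arrays only)
    birth_rate = 0.5,          # duplications / repeat / unit
    death_rate = 0.45,         # losses / repeat / unit
    truncation_rate = 0.25,    # terminal clippings / repeat / unit
    placement = "dispersed",   # or "arrayed"
    hybridization = list(),
    n_blocks = 20L,
    n_genes = 3L,
    gene_length = 400L,
    gene_both_retention = 0.4, # chance a hybrid keeps both parental gene copies
    hybrid_repeat_recomb = 0.3, # chance an offspring repeat is a parental chimera
    pseudogene_plants = 2L,    # forced CBC-pair mismatches per tip genome
    clones_per_strain = 12L,
    detect_threshold = 0.25,
    genome_length = 20000L,
    minus_strand_prob = 0.2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    .rdnadiv_error("rdnadiv_bad_config",
                   sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  rates <- c("mutation_rate", "homogenization_rate", "birth_rate", "death_rate",
             "truncation_rate")
  if (any(unlist(cfg[rates]) < 0)) {
    .rdnadiv_error("rdnadiv_bad_config", "rates must be non-negative")
  }
  probs <- c("wobble_accept", "cbc_accept", "mismatch_accept",
             "gene_both_retention", "detect_threshold", "minus_strand_prob")
  pv <- unlist(cfg[probs])
  if (any(pv < 0 | pv > 1)) {
    .rdnadiv_error("rdnadiv_bad_config", "probabilities must be in [0, 1]")
  }
  cfg$placement <- match.arg(cfg$placement, c("dispersed", "arrayed"))
  cfg$hybridization <- lapply(cfg$hybridization, function(ev) {
    stopifnot(length(ev$parents) == 2L, is.numeric(ev$time))
    if (is.null(ev$retention)) ev$retention <- 0.5
    ev
  })
  class(cfg) <- "simulation_config"
  cfg
}

#' Read a simulation configuration from a key-value file
#'
#' Accepts a YAML file (fields as in [simulation_config()]); the
#' `hybridization` field is a list of events with `parents`, `time`,
#' `retention`.
#'
#' @param path path to the config file.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulation_config, vals)
}

# deterministic two-hairpin reference structure for a unit of length L
.make_template <- function(L) {
  stopifnot(L >= 240L)
  db <- rep(".", L)
  stem <- 15L
  h1l <- 31L:(30L + stem); h1r <- (95L):(96L - stem)   # 31..45 with 95..81
  h2l <- 161L:(160L + stem); h2r <- (225L):(226L - stem)
  db[h1l] <- "("; db[sort(h1r)] <- ")"
  db[h2l] <- "("; db[sort(h2r)] <- ")"
  cbc <- rbind(c(35L, 126L - 35L), c(168L, 386L - 168L))  # partners: 91, 218
  loops <- data.frame(name = c("H1", "H2"),
                      start = c(31L, 161L), end = c(95L, 225L))
  list(dotbracket = paste(db, collapse = ""), cbc_pairs = cbc, loops = loops)
}

# ancestral sequence compatible with the structure (stems complementary)
.make_ancestor <- function(partner, L) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  done <- rep(FALSE, L)
  for (i in seq_len(L)) {
    j <- partner[i]
    if (!is.na(j) && !done[i]) {
      s[j] <- comp[[s[i]]]
      done[c(i, j)] <- TRUE
    }
  }
  s
}

.new_repeat <- function(env, seqv, origin, pos) {
  env$counter <- env$counter + 1L
  list(id = sprintf("rep%04d", env$counter), seq = seqv, origin = origin,
       pos = pos)
}

# propose and maybe accept one substitution in a repeat (or gene) sequence
.mutate_seq <- function(seqv, cfg, partner = NULL, cbc_key = NULL) {
  sites <- which(seqv != "-")
  if (!length(sites)) return(seqv)
  i <- sites[sample.int(length(sites), 1L)]
  b <- seqv[i]
  new <- if (stats::runif(1) < cfg$kappa / (cfg$kappa + 2)) .TRANSITION[[b]] else
    sample(setdiff(c("A", "C", "G", "T"), c(b, .TRANSITION[[b]])), 1L)
  accept <- TRUE
  if (!is.null(partner)) {
    j <- partner[i]
    if (!is.na(j) && seqv[j] != "-") {
      canonical <- paste0(new, seqv[j]) %in% .DNA_CANONICAL
      p <- if (canonical) cfg$wobble_accept
           else if (paste(sort(c(i, j)), collapse = "-") %in% cbc_key) cfg$cbc_accept
           else cfg$mismatch_accept
      accept <- stats::runif(1) < p
    }
  }
  if (accept) seqv[i] <- new
  seqv
}

# evolve one genome (repeats + genes) for dt time units
.evolve_genome <- function(g, dt, cfg, partner, cbc_key, env) {
  L <- cfg$repeat_length
  h_eff <- if (cfg$placement == "arrayed") cfg$homogenization_rate else 0
  per_repeat <- cfg$mutation_rate * L + h_eff + cfg$birth_rate +
    cfg$death_rate + cfg$truncation_rate
  t <- 0
  repeat {
    total <- length(g$repeats) * per_repeat
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t > dt) break
    r <- sample.int(length(g$repeats), 1L)
    ev <- sample(c("mut", "hom", "birth", "death", "trunc"), 1L,
                 prob = c(cfg$mutation_rate * L, h_eff, cfg$birth_rate,
                          cfg$death_rate, cfg$truncation_rate))
    if (ev == "mut") {
      g$repeats[[r]]$seq <- .mutate_seq(g$repeats[[r]]$seq, cfg, partner, cbc_key)
    } else if (ev == "hom") {
      if (length(g$repeats) > 1L) {
        donor <- sample(setdiff(seq_along(g$repeats), r), 1L)
        g$repeats[[r]]$seq <- g$repeats[[donor]]$seq
        g$repeats[[r]]$origin <- g$repeats[[donor]]$origin
      }
    } else if (ev == "birth") {
      child <- g$repeats[[r]]
      pos <- if (cfg$placement == "arrayed") child$pos else stats::runif(1)
      g$repeats[[length(g$repeats) + 1L]] <-
        .new_repeat(env, child$seq, child$origin, pos)
    } else if (ev == "death") {
      if (length(g$repeats) > 1L) g$repeats[[r]] <- NULL
    } else {
      sv <- g$repeats[[r]]$seq
      frac <- stats::runif(1, 0.1, 0.6)
      ncut <- max(1L, round(frac * L))
      if (stats::runif(1) < 0.5) sv[seq_len(ncut)] <- "-" else
        sv[(L - ncut + 1L):L] <- "-"
      g$repeats[[r]]$seq <- sv
    }
  }
  # genes: unconstrained transition-biased substitutions
  for (gi in seq_along(g$genes)) {
    for (ci in seq_along(g$genes[[gi]])) {
      nmut <- stats::rpois(1, cfg$mutation_rate * cfg$gene_length * dt)
      sv <- g$genes[[gi]][[ci]]$seq
      for (k in seq_len(nmut)) sv <- .mutate_seq(sv, cfg)
      g$genes[[gi]][[ci]]$seq <- sv
    }
  }
  g
}

# relabel repeat/gene origins with the name of the clade a lineage leads to
.clade_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tips <- ape::extract.clade(tree, node)$tip.label
  paste(sort(tips), collapse = "+")
}

# block-wise admixture of two genomes; recipient keeps blocks drawn toward
# itself with probability `retention`
.admix <- function(gA, gB, labA, labB, retention, cfg) {
  block <- function(pos) 1L + floor(pos * cfg$n_blocks)
  from_A <- stats::runif(cfg$n_blocks) < retention
  keepA <- Filter(function(r) from_A[block(r$pos)], gA$repeats)
  keepB <- Filter(function(r) !from_A[block(r$pos)], gB$repeats)
  keepA <- lapply(keepA, function(r) { r$origin <- labA; r })
  keepB <- lapply(keepB, function(r) { r$origin <- labB; r })
  reps <- c(keepA, keepB)
  if (!length(reps)) reps <- lapply(gA$repeats[1], function(r) { r$origin <- labA; r })
  # recombination between homeologous repeat variants while the hybrid
  # genome stabilizes: some repeats become two-segment parental chimeras,
  # the sequence-level footprint of reticulation
  if (cfg$hybrid_repeat_recomb > 0 && length(gA$repeats) && length(gB$repeats)) {
    L <- length(reps[[1]]$seq)
    for (ri in seq_along(reps)) {
      if (stats::runif(1) < cfg$hybrid_repeat_recomb) {
        donA <- gA$repeats[[sample.int(length(gA$repeats), 1L)]]$seq
        donB <- gB$repeats[[sample.int(length(gB$repeats), 1L)]]$seq
        bp <- sample.int(L - 1L, 1L)
        reps[[ri]]$seq <- c(donA[seq_len(bp)], donB[(bp + 1L):L])
        reps[[ri]]$origin <- paste0(labA, "x", labB)
      }
    }
  }
  genes <- vector("list", length(gA$genes))
  for (gi in seq_along(gA$genes)) {
    ca <- lapply(gA$genes[[gi]], function(cp) { cp$origin <- labA; cp })
    cb <- lapply(gB$genes[[gi]], function(cp) { cp$origin <- labB; cp })
    if (stats::runif(1) < cfg$gene_both_retention) {
      genes[[gi]] <- c(ca, cb)            # segmental diploidy: keep both
    } else {
      ka <- Filter(function(cp) from_A[block(cp$pos)], ca)
      kb <- Filter(function(cp) !from_A[block(cp$pos)], cb)
      kept <- c(ka, kb)
      if (!length(kept)) kept <- ca[1]
      genes[[gi]] <- kept
    }
  }
  list(repeats = reps, genes = genes)
}

# mechanistic functional status from the final sequence
.repeat_status <- function(seqv, cbc_pairs) {
  if (any(seqv == "-")) return("truncate")
  for (k in seq_len(nrow(cbc_pairs))) {
    i <- cbc_pairs[k, 1]; j <- cbc_pairs[k, 2]
    if (!paste0(seqv[i], seqv[j]) %in% .DNA_CANONICAL) return("pseudogene")
  }
  "intact"
}

#' Simulate a clade-scale dataset of repeats, genes, clones and consensus reads
#'
#' Evolves an ancestral repeat array and a set of single-copy genes down the
#' configured species tree. Substitutions are proposed at the configured
#' rate with transition bias and accepted according to their structural
#' consequence; homogenization overwrites a repeat with a same-array donor
#' (arrayed placement only); birth-and-death duplicates, deletes and
#' truncates repeats; hybridization events merge two coexisting lineages
#' block-wise. At the tips, a configurable number of pseudogenes is planted
#' by forcing a mismatch at a designated CBC pair, clones are sampled, and
#' the strain's Sanger-style consensus is emulated.
#'
#' @param config a `simulation_config`.
#' @return a `simulated_dataset` list: `config`, `taxa`, `structure`
#'   (a `secondary_structure` with `cbc_pairs`), `genomes` (per taxon:
#'   repeat list with id/seq/origin/pos/status), `genes`, `clones`
#'   (`seq_records`, aligned), `sanger` (`seq_records`, one per strain),
#'   `taxon_map`, `truth` (repeat/gene/placement tables), and
#'   `assemblies` (per-taxon contig `seq_records` with repeats and genes
#'   placed at recorded coordinates).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  tree <- ape::read.tree(text = cfg$tree)
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  root <- ntip + 1L

  tmpl <- .make_template(cfg$repeat_length)
  struct <- parse_dotbracket(paste(rep("N", cfg$repeat_length), collapse = ""),
                             tmpl$dotbracket, loops = tmpl$loops,
                             cbc_pairs = tmpl$cbc_pairs)
  partner <- struct$partner
  cbc_key <- apply(tmpl$cbc_pairs, 1, function(p) paste(sort(p), collapse = "-"))
  anc_seq <- .make_ancestor(partner, cfg$repeat_length)
  struct$reference <- .to_rna(paste(anc_seq, collapse = ""))

  env <- new.env(); env$counter <- 0L
  anc <- list(
    repeats = lapply(seq_len(cfg$n_repeats), function(i) {
      pos <- if (cfg$placement == "arrayed") (i - 0.5) / cfg$n_repeats / 10 else
        stats::runif(1)
      .new_repeat(env, anc_seq, "root", pos)
    }),
    genes = lapply(seq_len(cfg$n_genes), function(gi) {
      list(list(seq = sample(c("A", "C", "G", "T"), cfg$gene_length, replace = TRUE),
                origin = "root", pos = stats::runif(1)))
    })
  )

  # hybridization events: locate the carrying edge of each named lineage
  edge_of <- function(tip_label, t) {
    tip <- match(tip_label, tree$tip.label)
    if (is.na(tip)) .rdnadiv_error("rdnadiv_bad_config",
                                   sprintf("unknown lineage '%s'", tip_label))
    path <- ape::nodepath(tree, root, tip)
    for (k in seq_len(length(path) - 1L)) {
      e <- which(tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1L])
      if (depths[path[k]] < t && t <= depths[path[k + 1L]]) return(e)
    }
    NA_integer_
  }
  events <- lapply(cfg$hybridization, function(ev) {
    e1 <- edge_of(ev$parents[1], ev$time)
    e2 <- edge_of(ev$parents[2], ev$time)
    if (is.na(e1) || is.na(e2) || e1 == e2) {
      .rdnadiv_error("rdnadiv_bad_hybridization",
                     sprintf("lineages %s and %s do not coexist as distinct lineages at time %g",
                             ev$parents[1], ev$parents[2], ev$time))
    }
    list(time = ev$time, recipient = e1, donor = e2,
         retention = if (is.null(ev$retention)) 0.5 else ev$retention)
  })

  # chronological sweep over the tree
  ev_times <- vapply(events, `[[`, numeric(1), "time")
  breaks <- sort(unique(c(depths, ev_times)))
  breaks <- breaks[breaks > 0]
  edge_state <- vector("list", nrow(tree$edge))
  for (e in which(tree$edge[, 1] == root)) edge_state[[e]] <- anc
  cur <- 0
  tip_genomes <- vector("list", ntip)
  for (tb in breaks) {
    dt <- tb - cur
    for (e in seq_len(nrow(tree$edge))) {
      if (is.null(edge_state[[e]])) next
      t0 <- depths[tree$edge[e, 1]]; t1 <- depths[tree$edge[e, 2]]
      if (t0 <= cur && t1 >= tb && dt > 0) {
        edge_state[[e]] <- .evolve_genome(edge_state[[e]], dt, cfg, partner,
                                          cbc_key, env)
      }
    }
    # admixture exactly at tb
    for (ev in events) {
      if (abs(ev$time - tb) < 1e-12) {
        gA <- edge_state[[ev$recipient]]; gB <- edge_state[[ev$donor]]
        labA <- .clade_label(tree, tree$edge[ev$recipient, 2])
        labB <- .clade_label(tree, tree$edge[ev$donor, 2])
        edge_state[[ev$recipient]] <- .admix(gA, gB, labA, labB, ev$retention, cfg)
      }
    }
    # branchings / tips reached at tb
    for (e in seq_len(nrow(tree$edge))) {
      if (is.null(edge_state[[e]])) next
      child <- tree$edge[e, 2]
      if (abs(depths[child] - tb) < 1e-12) {
        g <- edge_state[[e]]
        edge_state[e] <- list(NULL)
        if (child <= ntip) {
          tip_genomes[[child]] <- g
        } else {
          for (e2 in which(tree$edge[, 1] == child)) edge_state[[e2]] <- g
        }
      }
    }
    cur <- tb
  }

  taxa <- tree$tip.label
  names(tip_genomes) <- taxa

  # plant pseudogenes: force a mismatch at a designated CBC pair
  for (tx in taxa) {
    g <- tip_genomes[[tx]]
    full <- which(vapply(g$repeats, function(r) !any(r$seq == "-"), logical(1)))
    nplant <- min(cfg$pseudogene_plants, length(full))
    if (nplant > 0L) {
      targets <- sample(full, nplant)
      for (r in targets) {
        k <- sample.int(nrow(tmpl$cbc_pairs), 1L)
        i <- tmpl$cbc_pairs[k, 1]; j <- tmpl$cbc_pairs[k, 2]
        pb <- g$repeats[[r]]$seq[j]
        bad <- setdiff(c("A", "C", "G", "T"),
                       c(g$repeats[[r]]$seq[i],
                         names(which(vapply(c(A="A",C="C",G="G",T="T"), function(b)
                           paste0(b, pb) %in% .DNA_CANONICAL, logical(1))))))
        if (length(bad)) g$repeats[[r]]$seq[i] <- sample(bad, 1L)
      }
    }
    tip_genomes[[tx]] <- g
  }

  # functional status, clones, sanger, truth tables
  for (tx in taxa) {
    tip_genomes[[tx]]$repeats <- lapply(tip_genomes[[tx]]$repeats, function(r) {
      r$status <- .repeat_status(r$seq, tmpl$cbc_pairs)
      r
    })
  }
  clone_rows <- list(); sanger_rows <- list(); truth_rep <- list()
  clone_truth <- list()
  for (ti in seq_along(taxa)) {
    tx <- taxa[ti]
    g <- tip_genomes[[tx]]
    reps <- g$repeats
    truth_rep[[tx]] <- data.frame(
      taxon = tx,
      repeat_id = vapply(reps, `[[`, "", "id"),
      origin = vapply(reps, `[[`, "", "origin"),
      status = vapply(reps, `[[`, "", "status"),
      pos = vapply(reps, `[[`, numeric(1), "pos"),
      stringsAsFactors = FALSE)
    # clones come from PCR amplicons: repeats missing a primer-flanked end
    # (truncated) do not amplify, so sampling is over full-length repeats
    amplifiable <- Filter(function(r) !any(r$seq == "-"), reps)
    if (!length(amplifiable)) amplifiable <- reps
    cl <- sample_clones(amplifiable,
                        min(cfg$clones_per_strain, length(amplifiable)),
                        seed = cfg$seed * 1000L + ti, taxon = tx)
    clone_rows[[tx]] <- cl$records
    clone_truth[[tx]] <- cl$truth
    m <- do.call(rbind, lapply(reps, `[[`, "seq"))
    sg <- sanger_emulation(m, detect_threshold = cfg$detect_threshold,
                           id = paste0(tx, "_sanger"))
    sr <- sg$record
    sr$taxon <- tx
    sanger_rows[[tx]] <- sr
  }
  clones <- do.call(rbind, clone_rows)
  class(clones) <- c("seq_records", "data.frame")
  rownames(clones) <- NULL
  sanger <- do.call(rbind, sanger_rows)
  class(sanger) <- c("seq_records", "data.frame")
  rownames(sanger) <- NULL
  taxon_map <- data.frame(id = clones$id, taxon = clones$taxon,
                          stringsAsFactors = FALSE)

  assemblies <- .place_genomes(tip_genomes, cfg)

  structure(list(config = cfg, taxa = taxa, structure = struct,
                 genomes = tip_genomes,
                 clones = clones, sanger = sanger, taxon_map = taxon_map,
                 truth = list(repeats = do.call(rbind, truth_rep),
                              clones = do.call(rbind, clone_truth),
                              placements = assemblies$truth),
                 assemblies = assemblies$contigs),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d taxa, %d clones, seed %d\n",
              length(x$taxa), nrow(x$clones), x$config$seed))
  invisible(x)
}

#' Sample cloned repeat sequences from a genome
#'
#' Uniform sampling of repeat copies, emulating the cloning and sequencing
#' of individual rDNA units. Clone ids carry the true repeat identity for
#' later evaluation.
#'
#' @param repeats list of repeat objects (a `simulated_dataset`
#'   `genomes[[taxon]]$repeats` entry).
#' @param n number of clones.
#' @param seed optional seed for reproducible sampling (RNG state is
#'   restored afterwards).
#' @param replace sample with replacement (required when `n` exceeds the
#'   repeat count).
#' @param taxon taxon label stamped on the records.
#' @return list with `records` (aligned `seq_records`, source `simulated`)
#'   and `truth` (data frame clone id / repeat id / status / origin).
#' @export
sample_clones <- function(repeats, n, seed = NULL, replace = FALSE,
                          taxon = "") {
  if (n > length(repeats) && !replace) {
    .rdnadiv_error("rdnadiv_bad_sample",
                   sprintf("cannot sample %d clones from %d repeats without replacement",
                           n, length(repeats)))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  idx <- sample.int(length(repeats), n, replace = replace)
  ids <- sprintf("%s_%s_clone%02d", taxon,
                 vapply(repeats[idx], `[[`, "", "id"), seq_len(n))
  res <- vapply(repeats[idx], function(r) paste(r$seq, collapse = ""), "")
  rec <- seq_records(id = ids, residues = res, taxon = taxon, source = "simulated")
  truth <- data.frame(id = ids,
                      repeat_id = vapply(repeats[idx], `[[`, "", "id"),
                      status = vapply(repeats[idx], function(r)
                        if (is.null(r$status)) NA_character_ else r$status, ""),
                      origin = vapply(repeats[idx], `[[`, "", "origin"),
                      taxon = taxon, stringsAsFactors = FALSE)
  list(records = rec, truth = truth)
}

# place repeats and genes on two background contigs per strain; truth table
# records 1-based coordinates and strands
.place_genomes <- function(tip_genomes, cfg) {
  contigs <- list(); truth <- list()
  for (tx in names(tip_genomes)) {
    g <- tip_genomes[[tx]]
    inserts <- list()
    for (r in g$repeats) {
      s <- paste(r$seq[r$seq != "-"], collapse = "")
      inserts[[length(inserts) + 1L]] <- list(id = r$id, kind = "repeat",
                                              pos = r$pos, seq = s)
    }
    for (gi in seq_along(g$genes)) {
      for (cp in g$genes[[gi]]) {
        inserts[[length(inserts) + 1L]] <- list(
          id = sprintf("gene%02d_%s", gi, substr(cp$origin, 1, 12)),
          kind = sprintf("gene%02d", gi), pos = cp$pos,
          seq = paste(cp$seq, collapse = ""))
      }
    }
    for (cname in c("c1", "c2")) {
      sel <- Filter(function(x) (x$pos < 0.5) == (cname == "c1"), inserts)
      sel <- sel[order(vapply(sel, `[[`, numeric(1), "pos"))]
      half_len <- max(cfg$genome_length %/% 2L,
                      sum(vapply(sel, function(x) nchar(x$seq), integer(1))) + 100L * (length(sel) + 1L))
      spacer_total <- half_len - sum(vapply(sel, function(x) nchar(x$seq), integer(1)))
      nspace <- length(sel) + 1L
      sp_len <- diff(floor(seq(0, spacer_total, length.out = nspace + 1L)))
      chunks <- character(0); coord <- 0L
      for (si in seq_along(sel)) {
        bg <- paste(sample(c("A", "C", "G", "T"), sp_len[si], replace = TRUE),
                    collapse = "")
        chunks <- c(chunks, bg)
        coord <- coord + nchar(bg)
        strand <- if (stats::runif(1) < cfg$minus_strand_prob) "-" else "+"
        ins <- if (strand == "-") revcomp(sel[[si]]$seq) else sel[[si]]$seq
        chunks <- c(chunks, ins)
        truth[[length(truth) + 1L]] <- data.frame(
          taxon = tx, contig = paste0(tx, "_", cname),
          id = sel[[si]]$id, kind = sel[[si]]$kind,
          start = coord + 1L, end = coord + nchar(ins), strand = strand,
          stringsAsFactors = FALSE)
        coord <- coord + nchar(ins)
      }
      chunks <- c(chunks, paste(sample(c("A", "C", "G", "T"), sp_len[nspace],
                                       replace = TRUE), collapse = ""))
      contigs[[paste0(tx, "_", cname)]] <- paste(chunks, collapse = "")
    }
  }
  rec <- seq_records(id = names(contigs), residues = unlist(contigs),
                     source = "simulated")
  rec$taxon <- sub("_c[12]$", "", rec$id)
  list(contigs = rec, truth = do.call(rbind, truth))
}

#' Emit the simulated genome assemblies as FASTA
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if needed); one FASTA per strain.
#' @return character vector of written paths, invisibly.
#' @export
emit_genome_fasta <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(dataset$taxa, function(tx) {
    sub <- dataset$assemblies[dataset$assemblies$taxon == tx, , drop = FALSE]
    p <- file.path(dir, paste0(tx, "_genome.fasta"))
    write_fasta(sub, p)
    p
  }, "")
  invisible(paths)
}

#' Emit the sampled clone sequences as FASTA (aligned; gaps mark truncation)
#'
#' @param dataset a `simulated_dataset`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
emit_clone_fasta <- function(dataset, path) {
  write_fasta(dataset$clones, path)
}

#' Emit ground-truth tables as TSV
#'
#' Writes `repeats.tsv` (repeat id, origin lineage, functional status),
#' `clones.tsv` (clone to repeat mapping) and `placements.tsv` (coordinates
#' of every planted repeat and gene copy) into `dir`, plus `taxon_map.tsv`
#' and the reference structure as a Vienna dot-bracket file.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
emit_truth_tables <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(repeats = file.path(dir, "repeats.tsv"),
             clones = file.path(dir, "clones.tsv"),
             placements = file.path(dir, "placements.tsv"),
             taxon_map = file.path(dir, "taxon_map.tsv"),
             structure = file.path(dir, "structure.dbn"))
  utils::write.table(dataset$truth$repeats, paths["repeats"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$clones, paths["clones"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$placements, paths["placements"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$taxon_map, paths["taxon_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_dotbracket(dataset$structure, paths["structure"])
  invisible(paths)
}
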