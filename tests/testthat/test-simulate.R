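test_that("configs validate fields and load from key-value files", {
  expect_error(simulation_config(nonsense = 1), class = "rdnadiv_bad_config")
  expect_error(simulation_config(mutation_rate = -1), class = "rdnadiv_bad_config")
  expect_error(simulation_config(wobble_accept = 2), class = "rdnadiv_bad_config")
  cfg <- fixture_config("admixed")
  expect_s3_class(cfg, "simulation_config")
  expect_length(cfg$hybridization, 1)
  expect_equal(cfg$hybridization[[1]]$parents, c("st1", "st3"))
})

test_that("datasets are byte-identical for a fixed (config, seed)", {
  cfg <- simulation_config(seed = 5, n_repeats = 6, clones_per_strain = 4,
                           genome_length = 4000)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$clones$residues, d2$clones$residues)
  expect_identical(d1$assemblies$residues, d2$assemblies$residues)
  expect_identical(d1$truth$repeats, d2$truth$repeats)
  expect_identical(d1$sanger$residues, d2$sanger$residues)
})

test_that("strong homogenization drives intragenomic diversity towards zero", {
  intra <- vapply(c(0, 10, 200), function(h) {
    cfg <- simulation_config(seed = 11, placement = "arrayed",
                             homogenization_rate = h, birth_rate = 0.1,
                             death_rate = 0.05, truncation_rate = 0.02,
                             pseudogene_plants = 0L)
    ds <- simulate_dataset(cfg)
    dm <- distance_matrix(alignment(ds$clones))
    mean(unlist(intra_inter_partition(dm, ds$taxon_map)$intra))
  }, numeric(1))
  expect_true(all(diff(intra) < 0))
  expect_lt(intra[3], 0.2)
})

test_that("without homogenization dispersed repeats keep diverging with time", {
  short <- simulation_config(seed = 13, homogenization_rate = 0,
    tree = "((st1:0.2,st2:0.2):0.1,(st3:0.2,st4:0.2):0.1);",
    pseudogene_plants = 0L, truncation_rate = 0)
  long <- simulation_config(seed = 13, homogenization_rate = 0,
    tree = "((st1:1.2,st2:1.2):0.6,(st3:1.2,st4:1.2):0.6);",
    pseudogene_plants = 0L, truncation_rate = 0)
  mi <- function(cfg) {
    ds <- simulate_dataset(cfg)
    dm <- distance_matrix(alignment(ds$clones))
    p <- intra_inter_partition(dm, ds$taxon_map)
    max(p$max_intra)
  }
  m_short <- mi(short); m_long <- mi(long)
  expect_gt(m_long, 0)
  expect_gt(m_long, m_short)
})

test_that("hybridization leaves both parental origin labels in the offspring", {
  ds <- simulate_dataset(fixture_config("admixed"))
  orig <- ds$truth$repeats$origin[ds$truth$repeats$taxon == "st1"]
  expect_true(any(grepl("^st1", orig)) && any(grepl("st3", orig)))
  expect_error(
    simulate_dataset(simulation_config(
      hybridization = list(list(parents = c("st1", "st2"), time = 0.1,
                                retention = 0.5)))),
    class = "rdnadiv_bad_hybridization")
})

test_that("clone sampling is uniform, reproducible and respects replacement", {
  ds <- simulate_dataset(simulation_config(seed = 3))
  reps <- ds$genomes$st1$repeats
  c1 <- sample_clones(reps, length(reps), seed = 99, taxon = "st1")
  expect_setequal(c1$truth$repeat_id, vapply(reps, `[[`, "", "id"))
  c2 <- sample_clones(reps, length(reps), seed = 99, taxon = "st1")
  expect_identical(c1$records$residues, c2$records$residues)
  expect_error(sample_clones(reps, length(reps) + 1),
               class = "rdnadiv_bad_sample")
  # uniformity: chi-square over 1000 draws with replacement
  draws <- sample_clones(reps, 1000, seed = 100, replace = TRUE)
  tab <- table(draws$truth$repeat_id)
  expect_length(tab, length(reps))
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(chi$p.value, 1e-4)
})

test_that("variable sites concentrate in unpaired segments under stem constraints", {
  ds <- simulate_dataset(simulation_config(seed = 23, pseudogene_plants = 0L))
  aln <- alignment(ds$clones)
  ref <- which(!grepl("-", ds$clones$residues))[1]
  sites <- find_variable_sites(aln, ds$structure, ref = ref)
  anchored <- sites[sites$context %in% c("paired", "unpaired"), ]
  frac_unpaired_sites <- mean(anchored$context == "unpaired")
  frac_unpaired_struct <- mean(is.na(ds$structure$partner))
  expect_gt(frac_unpaired_sites, frac_unpaired_struct)
})

test_that("emitted artifacts round-trip through the pipeline", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(simulation_config(seed = 29, n_repeats = 6,
                                           clones_per_strain = 4,
                                           genome_length = 5000))
  emit_genome_fasta(ds, dir)
  emit_clone_fasta(ds, file.path(dir, "clones.fasta"))
  paths <- emit_truth_tables(ds, dir)
  # clones re-read byte-identically
  back <- read_fasta(file.path(dir, "clones.fasta"))
  expect_identical(back$residues, ds$clones$residues)
  # structure round-trips
  st <- read_dotbracket(paths["structure"])
  expect_equal(st$partner, ds$structure$partner)
  # Sanger consensus re-emulated from the stored repeat pool is identical
  for (tx in ds$taxa) {
    m <- do.call(rbind, lapply(ds$genomes[[tx]]$repeats, `[[`, "seq"))
    re <- sanger_emulation(m, detect_threshold = ds$config$detect_threshold)
    expect_identical(re$record$residues,
                     ds$sanger$residues[ds$sanger$taxon == tx])
  }
  # genome FASTA + placements: re-scanning recovers every intact plant
  tx <- ds$taxa[2]
  genome <- read_fasta(file.path(dir, paste0(tx, "_genome.fasta")),
                       source = "genome")
  q <- seq_records("unit", chartr("U", "T", ds$structure$reference))
  hits <- scan_genome(genome, q)
  pl <- merge(ds$truth$placements[ds$truth$placements$taxon == tx &
                                    ds$truth$placements$kind == "repeat", ],
              ds$truth$repeats[, c("repeat_id", "status")],
              by.x = "id", by.y = "repeat_id")
  intact <- pl[pl$status != "truncate", ]
  found <- merge(intact, as.data.frame(hits), by = c("contig", "start"))
  expect_equal(nrow(found), nrow(intact))
})

test_that("pseudogene truth from clones matches the structural flagging rule", {
  ds <- simulate_dataset(simulation_config(seed = 7))
  aln <- alignment(ds$clones)
  ref <- which(!grepl("-", ds$clones$residues))[1]
  sites <- find_variable_sites(aln, ds$structure, ref = ref)
  rep <- flag_pseudogenes(aln, ds$structure, sites, ref = ref)
  truth <- ds$truth$clones
  pred <- rep$flags$flagged[match(truth$id, rep$flags$id)]
  expect_identical(pred, truth$status == "pseudogene")
})
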