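# Synthetic data generator: determinism, conservation, reference invariants.

small_config <- function(seed = 3L) {
  simulation_config(seed = seed,
                    n_samples_per_specimen = c(plasma = 4L, stool = 3L,
                                               urine = 3L, cervical = 2L),
                    depth = 2000L)
}

test_that("same config and seed reproduce reference and cohort byte for byte", {
  cfg <- small_config()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  b1 <- build_reference(cfg); b2 <- build_reference(cfg)
  expect_identical(b1, b2)
  p1 <- write_reference(b1, file.path(d1, "ref"))
  p2 <- write_reference(b2, file.path(d2, "ref"))
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
                     readBin(p2[[k]], "raw", file.size(p2[[k]])),
                     label = paste("bytes of", k))
  }
  s1 <- simulate_cohort(cfg, file.path(d1, "reads"), bundle = b1)
  s2 <- simulate_cohort(cfg, file.path(d2, "reads"), bundle = b2)
  expect_identical(s1$truth$counts, s2$truth$counts)
  for (f in names(s1$fastq)) {
    expect_identical(readLines(s1$fastq[[f]]), readLines(s2$fastq[[f]]))
  }
})

test_that("reference bundle satisfies its structural invariants", {
  cfg <- small_config()
  b <- build_reference(cfg)
  # planted inventory
  expect_gte(length(b$precursors),
             cfg$n_common_mirnas + sum(cfg$n_specific_per_specimen))
  expect_gte(sum(b$sncrna$class == "piRNA"), 20)
  expect_gte(sum(b$sncrna$class == "tRNA"), 10)
  expect_gte(sum(b$sncrna$source == "GENCODE" & b$sncrna$length > 70), 5)
  # mature arms inside their precursor
  plen <- nchar(b$precursors)[b$mature$precursor]
  expect_true(all(b$mature$start >= 0 & b$mature$end <= plen))
  # homologous pair: distinct coordinates, identical sequence
  hom <- b$sncrna[!is.na(b$sncrna$homolog_group)]
  expect_gte(nrow(hom), 2)
  expect_identical(hom$sequence[1], hom$sequence[2])
  expect_false(identical(hom$start[1], hom$start[2]) &&
                 identical(hom$contig[1], hom$contig[2]))
  # annotation sequences are substrings of their contig (strand-aware)
  extr <- ifelse(b$sncrna$strand == "-",
                 vapply(substr(b$genome[b$sncrna$contig], b$sncrna$start + 1,
                               b$sncrna$end), oracle_revcomp, ""),
                 substr(b$genome[b$sncrna$contig], b$sncrna$start + 1,
                        b$sncrna$end))
  expect_identical(unname(extr), b$sncrna$sequence)
})

test_that("requesting more planted miRNAs than precursors is a config error", {
  expect_error(simulation_config(n_precursors = 10L), "configuration error")
})

test_that("true counts conserve depth exactly and planted ids exist", {
  cfg <- small_config(seed = 9L)
  b <- build_reference(cfg)
  tr <- simulate_true_counts(cfg, b)
  expect_true(all(colSums(tr$counts) == cfg$depth))
  planted <- c(tr$sets$mirna$common, unlist(tr$sets$mirna$specific),
               tr$sets$mirna$paired)
  expect_true(all(planted %in% c(b$mature$mature)))
  expect_true(all(expand_unit_ids(tr, tr$sets$snc_common) %in% b$sncrna$id))
})

test_that("each FASTQ holds exactly depth records with provenance-encoded ids", {
  cfg <- small_config(seed = 5L)
  sim <- simulate_cohort(cfg, file.path(tempdir(), "prov"))
  r <- read_fastq(sim$fastq[[1]])
  expect_equal(nrow(r), cfg$depth)
  tfi <- truth_from_ids(r$id)
  expect_setequal(unique(tfi$sample_id), names(sim$fastq)[1])
  # per-unit read counts in the file equal the truth matrix column
  tab <- table(tfi$unit)
  nonzero <- tr_col <- sim$truth$counts[, names(sim$fastq)[1]]
  nonzero <- tr_col[tr_col > 0]
  expect_equal(as.integer(tab[names(nonzero)]), unname(nonzero))
})

test_that("zero batch offsets leave per-feature means comparable across studies", {
  cfg <- simulation_config(seed = 21L,
                           n_samples_per_specimen = c(plasma = 30L),
                           depth = 20000L,
                           batch_log_offsets = c(study1 = 0, study2 = 0, study3 = 0))
  b <- build_reference(cfg)
  tr <- simulate_true_counts(cfg, b)
  common <- tr$sets$mirna$common
  by_study <- split(seq_len(nrow(tr$samples)), tr$samples$batch)
  m <- vapply(by_study, function(ix) rowMeans(tr$counts[common, ix]),
              numeric(length(common)))
  # log-means agree across studies within sampling error: each study mean of
  # 10 samples has SE ~ sigma_log10/sqrt(10) ~ 0.08, so a range of 3 means
  # beyond 0.4 (~5 SE) would indicate a residual systematic offset
  spread <- apply(log10(m), 1, function(v) max(v) - min(v))
  expect_lt(max(spread), 0.4)
})

test_that("planted subject-level correlation materializes near rho", {
  # Monte-Carlo on the generator alone, judged across seeds
  hits <- 0L
  for (seed in 1:5) {
    cfg <- simulation_config(seed = 100L + seed,
                             n_samples_per_specimen = c(plasma = 46L, urine = 46L),
                             depth = 20000L,
                             batch_log_offsets = c(study2 = 0))
    b <- build_reference(cfg)
    tr <- simulate_true_counts(cfg, b)
    f <- tr$sets$mirna$paired[1]
    pl <- tr$samples$sample_id[tr$samples$specimen == "plasma"]
    ur <- tr$samples$sample_id[tr$samples$specimen == "urine"]
    r <- cor(log10(tr$counts[f, pl] + 1), log10(tr$counts[f, ur] + 1))
    hits <- hits + (abs(r - cfg$rho) <= 0.25)
  }
  expect_gte(hits, 4L)
})
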