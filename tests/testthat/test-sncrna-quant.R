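# Phase 2: genome alignment, size selection, annotation assignment, counting.

bundle <- tiny_bundle()
genome <- bundle$genome
snc <- bundle$sncrna
frag <- function(id, from, len) {
  s <- snc$sequence[snc$id == id]
  substr(s, from + 1, from + len)
}

test_that("exact substring and reverse-complement reads map with the right strand", {
  tr <- snc[snc$id == "tRNA-a", ]
  fwd <- substr(genome[["chrT"]], tr$start + 5, tr$start + 44)  # inside tRNA
  h <- align_to_genome(make_reads(fwd), genome)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, tr$start + 4)
  expect_equal(h$end, tr$start + 44)
  expect_equal(h$strand, "+")
  h2 <- align_to_genome(make_reads(oracle_revcomp(fwd)), genome)
  expect_equal(h2$start, tr$start + 4)
  expect_equal(h2$strand, "-")
})

test_that("genome aligner agrees with the exhaustive two-strand oracle", {
  set.seed(41)
  toy <- setNames(random_dna(2, 150), c("c1", "c2"))
  for (i in 1:500) {
    kind <- i %% 3
    if (kind == 0) {
      read <- random_dna(1, 40)  # expected: no hit on an unrelated genome
    } else {
      ref <- sample(2, 1)
      off <- sample(0:(150 - 35), 1)
      read <- substr(toy[[ref]], off + 1, off + 35)
      for (p in sample(35, sample(0:3, 1)))
        read <- mutate_at(read, p, sample(c("A", "C", "G", "T"), 1))
      if (kind == 2) read <- oracle_revcomp(read)
    }
    got <- align_to_genome(make_reads(read), toy, max_mismatches = 2)
    want <- oracle_align(read, toy, 2, both_strands = TRUE)
    expect_equal(nrow(got), nrow(want), label = paste("case", i))
    if (nrow(want)) {
      expect_setequal(paste(got$contig, got$start, got$strand, got$mismatches),
                      paste(names(toy)[want$ref], want$start, want$strand,
                            want$mismatches))
    }
  }
})

test_that("size selection keeps GENCODE <= 70 inclusively and all DASHR piRNA/tRNA", {
  a <- data.table::data.table(
    id = c("g70", "g71", "pi", "tr81", "dashr_sno"),
    class = c("snoRNA", "misc_RNA", "piRNA", "tRNA", "snoRNA"),
    source = c("GENCODE", "GENCODE", "DASHR", "DASHR", "DASHR"),
    length = c(70L, 71L, 31L, 81L, 65L))
  kept <- select_quantifiable_annotations(a)
  expect_setequal(kept$id, c("g70", "pi", "tr81"))
  a$length[1] <- NA
  expect_error(select_quantifiable_annotations(a), "length")
})

test_that("assignment needs 90% coverage on the same strand", {
  quant <- select_quantifiable_annotations(snc)
  # fully inside piR-a
  h <- align_to_genome(make_reads(frag("piR-a", 0, 31)), genome)
  asg <- assign_to_annotations(h, quant)
  expect_setequal(asg$id, c("piR-a", "piR-b"))  # homolog twin ties
  # a 40-nt read overlapping the tRNA by ~50% stays unassigned
  tr <- snc[snc$id == "tRNA-a", ]
  half <- substr(genome[["chrT"]], tr$start + 57, tr$start + 57 + 39)
  h2 <- align_to_genome(make_reads(half), genome)
  expect_equal(nrow(assign_to_annotations(h2, quant)), 0)
  # same fragment passes at a permissive threshold
  expect_gt(nrow(assign_to_annotations(h2, quant, min_overlap_fraction = 0.4)), 0)
})

test_that("strand discipline: flipping the annotation strand zeroes its count", {
  quant <- select_quantifiable_annotations(snc)
  h <- align_to_genome(make_reads(frag("tRNA-a", 10, 40)), genome)
  expect_equal(assign_to_annotations(h, quant)$id, "tRNA-a")
  flipped <- data.table::copy(quant)
  flipped$strand[flipped$id == "tRNA-a"] <- "-"
  expect_equal(nrow(assign_to_annotations(h, flipped)), 0)
})

test_that("minus-strand annotations are counted from sense reads", {
  # sno-long sits on the minus strand; its sense fragment maps strand '-'
  h <- align_to_genome(make_reads(frag("sno-long", 5, 40)), genome)
  expect_equal(h$strand, "-")
  # it is excluded by size selection, so quantification ignores it
  quant <- select_quantifiable_annotations(snc)
  expect_equal(nrow(assign_to_annotations(h, quant)), 0)
  # but against the unselected table it is assigned
  expect_equal(assign_to_annotations(h, snc)$id, "sno-long")
})

test_that("counting matrix, homolog equality and the phase-2 partition", {
  samples <- data.table::data.table(
    sample_id = c("s1", "s2"), specimen = "urine", batch = "b",
    subject_id = c("u1", "u2"))
  pools <- list(
    s1 = make_reads(c(rep(frag("piR-a", 0, 31), 12), rep(frag("tRNA-a", 3, 45), 5),
                      random_dna(4, 40))),
    s2 = make_reads(c(rep(frag("piR-a", 0, 31), 7), rep(frag("sno-long", 5, 40), 3))))
  res <- build_sncrna_counts(pools, bundle, samples)
  cm <- SummarizedExperiment::assay(res$se, "counts")
  expect_equal(cm["piR-a", ], cm["piR-b", ])           # exact homolog equality
  expect_equal(unname(cm["piR-a", ]), c(12, 7))
  expect_equal(unname(cm["tRNA-a", "s1"]), 5)
  rp <- res$report
  expect_equal(rp$n_assigned + rp$n_unassigned_mapped + rp$n_genome_unmapped,
               rp$n_pool)
  expect_equal(rp$n_genome_unmapped, c(4, 0))
  expect_equal(rp$n_unassigned_mapped, c(0, 3))  # the size-excluded snoRNA reads
})

test_that("an empty phase-2 pool warns and yields a zero column", {
  samples <- data.table::data.table(
    sample_id = c("s1", "s2"), specimen = "urine", batch = "b",
    subject_id = c("u1", "u2"))
  pools <- list(s1 = make_reads(rep(frag("piR-a", 0, 31), 3)),
                s2 = make_reads(character(0)))
  expect_warning(res <- build_sncrna_counts(pools, bundle, samples), "empty")
  cm <- SummarizedExperiment::assay(res$se, "counts")
  expect_true(all(cm[, "s2"] == 0))
})
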