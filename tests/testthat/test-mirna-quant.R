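# Phase 1: precursor alignment, mature assignment, counting, isomiRs.

bundle <- tiny_bundle()
prec <- bundle$precursors
arm <- function(m) {
  row <- bundle$mature[bundle$mature$mature == m, ]
  substr(prec[[row$precursor]], row$start + 1, row$end)
}

test_that("exact substring reads yield a single zero-mismatch hit at the right offset", {
  h <- align_to_precursors(make_reads(arm("mir-x-5p")), prec)
  expect_equal(nrow(h), 1)
  expect_equal(h$precursor, "mir-x")
  expect_equal(h$offset, 5)
  expect_equal(h$mismatches, 0)
})

test_that("the mismatch cap is strict: 3 ok, 4 is no hit", {
  r3 <- mutate_at(mutate_at(mutate_at(arm("mir-x-5p"), 2, "T"), 8, "C"), 14, "A")
  r4 <- mutate_at(r3, 20, "G")
  # guard against accidental matches created by mutation
  expect_equal(oracle_mm(r3, prec[["mir-x"]], 5), 3)
  expect_equal(oracle_mm(r4, prec[["mir-x"]], 5), 4)
  expect_equal(align_to_precursors(make_reads(r3), prec)$mismatches, 3)
  expect_equal(nrow(align_to_precursors(make_reads(r4), prec)), 0)
})

test_that("a read matching two precursors exactly gets two equal-score hits", {
  shared <- "ACGGTTCAGATCCGATAAGCTG"
  two <- c(a = paste0("CCTTT", shared, "GAAAC"),
           b = paste0("TGGAT", shared, "CTTGA"))
  h <- align_to_precursors(make_reads(shared), two)
  expect_equal(nrow(h), 2)
  expect_setequal(h$precursor, c("a", "b"))
  expect_equal(unique(h$score), nchar(shared))
})

test_that("aligner agrees with the exhaustive scan oracle on random instances", {
  set.seed(31)
  refs <- setNames(random_dna(3, 70), c("p1", "p2", "p3"))
  for (i in 1:500) {
    if (i %% 3 == 0) {
      read <- random_dna(1, sample(18:30, 1))        # mostly no hit
    } else {
      ref <- sample(3, 1)
      off <- sample(0:(70 - 22), 1)
      read <- substr(refs[[ref]], off + 1, off + 22)
      nmut <- sample(0:4, 1)
      for (p in sample(22, nmut)) read <- mutate_at(read, p, sample(c("A", "C", "G", "T"), 1))
    }
    got <- align_to_precursors(make_reads(read), refs, max_mismatches = 3)
    want <- oracle_align(read, refs, 3, both_strands = FALSE)
    expect_equal(nrow(got), nrow(want), label = paste("case", i))
    if (nrow(want)) {
      expect_setequal(paste(got$precursor, got$offset, got$mismatches),
                      paste(names(refs)[want$ref], want$start, want$mismatches))
    }
  }
})

test_that("raising the mismatch cap never loses aligned reads", {
  set.seed(32)
  refs <- setNames(random_dna(2, 80), c("p1", "p2"))
  reads <- make_reads(c(random_dna(30, 22),
                        vapply(1:30, function(i) {
                          r <- substr(refs[[1]], 11, 32)
                          for (p in sample(22, sample(0:5, 1)))
                            r <- mutate_at(r, p, sample(c("A", "C", "G", "T"), 1))
                          r
                        }, "")))
  n_aligned <- vapply(0:4, function(mm)
    length(unique(align_to_precursors(reads, refs, mm)$read_id)), 0L)
  expect_true(all(diff(n_aligned) >= 0))
})

test_that("high-N reads are skipped and counted, not errors", {
  r <- make_reads(c(arm("mir-x-5p"), gsub("[ACGT]", "N", arm("mir-x-5p"))))
  h <- align_to_precursors(r, prec)
  expect_equal(nrow(h), 1)
  expect_equal(attr(h, "n_skipped_N"), 1L)
})

test_that("mature assignment follows the half-read overlap rule", {
  mk_hit <- function(offset, length) {
    data.table::data.table(read_id = "r", precursor = "mir-x",
                           offset = offset, length = length,
                           mismatches = 0L, score = length)
  }
  ma <- bundle$mature
  # identity with the 5p interval
  expect_equal(assign_mature(mk_hit(5L, 22L), ma)$mature, "mir-x-5p")
  # +2 shift into the arm: overlap 20/22 -> still 5p
  a <- assign_mature(mk_hit(7L, 22L), ma)
  expect_equal(a$mature, "mir-x-5p")
  expect_equal(a$d5, 2L)
  # centred on the loop: < 50% overlap with both arms -> unassigned
  expect_true(is.na(assign_mature(mk_hit(20L, 22L), ma)$mature))
})

test_that("counting: homogeneous sample, multi-mapping, and the partition identity", {
  samples <- data.table::data.table(
    sample_id = c("s1", "s2"), specimen = c("plasma", "stool"),
    batch = "b1", subject_id = c("u1", "u2"))
  reads <- list(
    s1 = make_reads(rep(arm("mir-x-5p"), 100)),
    s2 = make_reads(c(rep(arm("mir-y-3p"), 40), random_dna(10, 25))))
  res <- build_mirna_counts(reads, bundle, samples)
  cm <- SummarizedExperiment::assay(res$se, "counts")
  expect_equal(cm["mir-x-5p", "s1"], 100)
  expect_equal(sum(cm[, "s1"]), 100)
  expect_equal(cm["mir-y-3p", "s2"], 40)
  expect_equal(res$report$n_aligned + res$report$n_unmapped,
               res$report$n_input)
  expect_equal(nrow(res$unmapped$s2), 10)

  # a read tied between two homologous precursors increments both matures
  twin <- bundle
  twin$precursors <- c(twin$precursors, `mir-x2` = twin$precursors[["mir-x"]])
  twin$mature <- rbind(twin$mature, data.table::data.table(
    mature = c("mir-x2-5p", "mir-x2-3p"), precursor = "mir-x2",
    start = c(5L, 35L), end = c(27L, 57L)))
  res2 <- build_mirna_counts(list(s1 = make_reads(rep(arm("mir-x-5p"), 7))),
                             twin, samples[1])
  cm2 <- SummarizedExperiment::assay(res2$se, "counts")
  expect_equal(cm2["mir-x-5p", "s1"], 7)
  expect_equal(cm2["mir-x2-5p", "s1"], 7)
  expect_equal(res2$report$n_aligned, 7)
})

test_that("isomiR calling classifies variants and applies the strict support boundary", {
  samples <- data.table::data.table(
    sample_id = c("s1", "s2"), specimen = c("stool", "stool"),
    batch = "b", subject_id = c("u1", "u2"))
  p <- prec[["mir-x"]]
  canonical <- arm("mir-x-5p")
  shift5 <- substr(p, 5, 27)            # starts 1 nt upstream: d5 = -1, d3 = 0
  shift3 <- substr(p, 6, 29)            # ends 2 nt downstream: d3 = +2
  mm1 <- mutate_at(canonical, 10, "T")  # internal mismatch
  reads <- list(s1 = make_reads(c(rep(canonical, 50), rep(shift5, 30),
                                  rep(shift3, 21), rep(mm1, 20))),
                s2 = make_reads(c(rep(canonical, 50), rep(shift5, 30),
                                  rep(shift3, 21), rep(mm1, 20))))
  res <- build_mirna_counts(reads, bundle, samples)
  calls <- call_isomirs(res$isomir_detail, samples, support_threshold = 20)
  expect_false(any(calls$variant_class == "canonical"))
  s5 <- calls[calls$d5 == -1L & calls$d3 == 0L]
  expect_equal(s5$variant_class, "5p_shift")
  expect_equal(s5$median_stool, 30)
  s3 <- calls[calls$d3 == 2L & calls$d5 == 0L]
  expect_equal(s3$variant_class, "3p_shift")
  # internal mismatch group has median exactly 20 -> excluded (strict >)
  expect_false(any(calls$variant_class == "internal_mismatch"))
  # raise it to 21 -> included
  reads21 <- lapply(reads, function(r)
    rbind(r, make_reads(mm1, ids = "extra")))
  res21 <- build_mirna_counts(reads21, bundle, samples)
  calls21 <- call_isomirs(res21$isomir_detail, samples, support_threshold = 20)
  im <- calls21[calls21$variant_class == "internal_mismatch"]
  expect_equal(nrow(im), 1)
  expect_equal(im$median_stool, 21)
  expect_equal(im$n_mismatches, 1L)
})
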