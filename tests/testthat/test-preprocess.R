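# Adapter trimming, quality and length filters, per-sample report.

adapter <- "AGATCGGAAGAGC"

test_that("trim_adapter removes a full adapter and leaves adapterless reads alone", {
  insert <- "ACGTACGTACGTACGT"
  r <- make_reads(c(paste0(insert, adapter),
                    "TTTTGGGGCCCCAAAATTTTGGGG",
                    paste0(adapter, "ACGTACGT")))
  out <- trim_adapter(r, adapter)
  expect_identical(out$sequence[1], insert)
  expect_true(out$trimmed[1])
  expect_identical(out$sequence[2], r$sequence[2])
  expect_false(out$trimmed[2])
  # adapter at position 0: empty insert, caught later by the length filter
  expect_identical(out$sequence[3], "")
  expect_identical(out$quality[3], "")
  expect_false(length_filter(out)[3])
})

test_that("trim_adapter agrees with the exhaustive scan oracle", {
  set.seed(77)
  for (i in 1:1000) {
    len <- sample(16:40, 1)
    seq <- random_dna(1, len)
    # half the cases get a (possibly mutated) adapter planted at a random spot
    if (i %% 2 == 0) {
      pos <- sample(0:(len - 4), 1)
      ad_part <- substr(adapter, 1, min(nchar(adapter), len - pos))
      substr(seq, pos + 1, pos + nchar(ad_part)) <- ad_part
    }
    got <- trim_adapter(make_reads(seq), adapter, min_overlap = 3,
                        max_error_rate = 0.1)
    expect_identical(nchar(got$sequence),
                     oracle_trim(seq, adapter, 3, 0.1),
                     label = paste("case", i, seq))
  }
})

test_that("quality filter uses the mean Phred score with a strict < threshold", {
  allI <- make_reads("ACGTACGTAC", qual = strrep("I", 10))   # Q40
  allBang <- make_reads("ACGTACGTAC", qual = strrep("!", 10)) # Q0
  expect_true(quality_filter(allI))
  expect_false(quality_filter(allBang))
  # 10 bases at Q29 + 10 at Q31 -> mean exactly 30.0 -> pass (not < 30)
  q <- paste0(strrep(rawToChar(as.raw(33 + 29)), 10),
              strrep(rawToChar(as.raw(33 + 31)), 10))
  expect_true(quality_filter(make_reads(random_dna(1, 20), qual = q)))
  expect_error(quality_filter(make_reads("ACGT", qual = "ABÉD")),
               "non-printable")
})

test_that("length filter boundary: 14 discarded, 15 kept at min_length 15", {
  r <- make_reads(c(random_dna(1, 14), random_dna(1, 15), ""))
  expect_identical(length_filter(r, 15L), c(FALSE, TRUE, FALSE))
})

test_that("preprocess_sample applies trim -> quality -> length and its counters add up", {
  set.seed(11)
  # 83 clean with adapter, 10 adapterless, 5 low-quality, 2 too short
  clean <- paste0(random_dna(83, 22), adapter, random_dna(83, 5))
  noad <- random_dna(10, 30)
  lowq <- paste0(random_dna(5, 22), adapter)
  short <- paste0(random_dna(2, 10), adapter, random_dna(2, 4))
  reads <- make_reads(c(clean, noad, lowq, short))
  reads$quality[94:98] <- strrep("#", nchar(reads$sequence[94:98]))  # Q2
  res <- preprocess_sample(reads, adapter = adapter)
  expect_equal(res$report$n_input, 100)
  expect_equal(res$report$n_discarded_low_quality, 5)
  expect_equal(res$report$n_discarded_short, 2)
  expect_equal(res$report$n_retained, 93)
  expect_equal(res$report$n_retained + res$report$n_discarded_short +
                 res$report$n_discarded_low_quality, res$report$n_input)
})

test_that("empty FASTQ yields all-zero counters", {
  f <- tempfile(fileext = ".fastq")
  writeLines(character(0), f)
  res <- preprocess_sample(f)
  expect_equal(res$report$n_input, 0)
  expect_equal(res$report$n_retained, 0)
})

test_that("conservation holds on random inputs and preprocessing is idempotent", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    seqs <- random_dna(n, sample(10:45, n, replace = TRUE))
    with_ad <- runif(n) < 0.5
    seqs[with_ad] <- paste0(seqs[with_ad], adapter)
    reads <- make_reads(seqs)
    lowq <- runif(n) < 0.2
    reads$quality[lowq] <- strrep("#", nchar(reads$sequence[lowq]))
    res <- preprocess_sample(reads, adapter = adapter)
    expect_equal(res$report$n_retained + res$report$n_discarded_short +
                   res$report$n_discarded_low_quality, n)
  }
})

test_that("preprocessing an already-clean read set changes nothing", {
  set.seed(13)
  seqs <- random_dna(200, sample(16:40, 200, replace = TRUE))
  clean <- seqs[vapply(seqs, oracle_trim, 0, adapter = adapter,
                       min_overlap = 3, max_error_rate = 0.1) == nchar(seqs)]
  expect_gt(length(clean), 50)
  reads <- make_reads(clean)
  res <- preprocess_sample(reads, adapter = adapter)
  expect_identical(res$reads$sequence, reads$sequence)
  expect_equal(res$report$n_retained, nrow(reads))
  expect_equal(res$report$n_adapter_trimmed, 0)
})

test_that("malformed reads are rejected with the offending id", {
  bad <- data.table::data.table(id = "oops", sequence = "ACGT", quality = "FFF")
  expect_error(trim_adapter(bad, adapter), "oops")
})
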