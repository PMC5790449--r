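# Independent R-only oracles: exhaustive scans and brute-force statistics,
# deliberately separate from the package's C++/vectorized paths.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# count mismatches of read against ref starting at 0-based offset
oracle_mm <- function(read, ref, offset) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(substr(ref, offset + 1, offset + nchar(read)), "")[[1]]
  sum(r != f)
}

# all best hits of a read over refs (named), optionally both strands
oracle_align <- function(read, refs, max_mm, both_strands = FALSE) {
  rows <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (st in strands) {
    rd <- if (st == "+") read else oracle_revcomp(read)
    for (ri in seq_along(refs)) {
      ref <- refs[[ri]]
      maxoff <- nchar(ref) - nchar(read)
      if (maxoff < 0) next
      for (off in 0:maxoff) {
        mm <- oracle_mm(rd, ref, off)
        if (mm <= max_mm) {
          rows[[length(rows) + 1]] <- data.frame(
            ref = ri, start = off, strand = st, mismatches = mm)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(ref = integer(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[out$mismatches == min(out$mismatches), , drop = FALSE]
}

# leftmost adapter trim position by exhaustive scan
oracle_trim <- function(seq, adapter, min_overlap, max_error_rate) {
  len <- nchar(seq)
  for (pos in 0:(len - 1)) {
    overlap <- min(nchar(adapter), len - pos)
    if (overlap < min_overlap) break
    mm <- sum(strsplit(substr(seq, pos + 1, pos + overlap), "")[[1]] !=
                strsplit(substr(adapter, 1, overlap), "")[[1]])
    if (mm <= floor(max_error_rate * overlap)) return(pos)
  }
  len
}

oracle_median <- function(v) {  # sort-based, avoids stats::median
  s <- sort(v); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_mad <- function(x) oracle_median(abs(x - oracle_median(x)))

# brute-force median-of-ratios size factors with explicit loops
oracle_size_factors <- function(m) {
  pos_rows <- which(apply(m, 1, function(r) all(r > 0)))
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(0)
    for (i in pos_rows) {
      geo <- prod(m[i, ])^(1 / ncol(m))
      ratios <- c(ratios, m[i, j] / geo)
    }
    out[j] <- median(ratios)
  }
  out
}

mutate_at <- function(s, pos, to) { substr(s, pos, pos) <- to; s }

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = ""), "")
}

# hand-built micro reference: two precursors with known arms, one genome
# contig embedding a homologous piRNA pair, a tRNA and a long snoRNA.
# All embedded sequences are aperiodic so exact reads have unique best hits.
tiny_bundle <- function() {
  arm_x5 <- "ACGGTTCAGATCCGATAAGCTG"
  arm_x3 <- "TTCAGGCATAACGGTCAGTCCA"
  arm_y5 <- "GACCTTAGCATGGAATCCGTTG"
  arm_y3 <- "CGTTAAGGCTACGATCCATGGA"
  p1 <- paste0("GGGCG", arm_x5, "TTGATTCT", arm_x3, "GGTGG")
  p2 <- paste0("AACTA", arm_y5, "CCAGTCCC", arm_y3, "ATAGA")
  precursors <- c(`mir-x` = p1, `mir-y` = p2)
  mature <- data.table::data.table(
    mature = c("mir-x-5p", "mir-x-3p", "mir-y-5p", "mir-y-3p"),
    precursor = c("mir-x", "mir-x", "mir-y", "mir-y"),
    start = c(5L, 35L, 5L, 35L),
    end = c(27L, 57L, 27L, 57L))
  pir_seq <- "ACCGGTTAACGTGCATCCGAATTGCAGGCTA"   # 31 nt
  set.seed(424243)
  trna_seq <- random_dna(1, 76)
  sno_seq <- random_dna(1, 80)                  # > 70 nt, excluded by size cut
  spacer <- function(n) strrep("A", n)
  contig <- paste0(spacer(30), pir_seq, spacer(25), pir_seq, spacer(20),
                   trna_seq, spacer(35), oracle_revcomp(sno_seq), spacer(30))
  starts <- c(30L, 86L, 137L, 248L)
  snc <- data.table::data.table(
    id = c("piR-a", "piR-b", "tRNA-a", "sno-long"),
    class = c("piRNA", "piRNA", "tRNA", "snoRNA"),
    source = c("DASHR", "DASHR", "DASHR", "GENCODE"),
    contig = "chrT",
    start = starts,
    end = starts + c(31L, 31L, 76L, 80L),
    strand = c("+", "+", "+", "-"),
    length = c(31L, 31L, 76L, 80L),
    sequence = c(pir_seq, pir_seq, trna_seq, sno_seq),
    homolog_group = c("homolog-01", "homolog-01", NA, NA))
  structure(list(genome = c(chrT = contig), precursors = precursors,
                 mature = mature, sncrna = snc, mirna_sets = NULL),
            class = "reference_bundle")
}

make_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                       qual = strrep("F", nchar(seqs))) {
  data.table::data.table(id = ids, sequence = seqs, quality = qual)
}
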