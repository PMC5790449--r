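#' Adapter trimming
#'
#' Truncates each read at the leftmost position where a prefix of the 3'
#' adapter matches, including partial (suffix) overlap at the read end.
#' A match requires an overlap of at least `min_overlap` bases and a mismatch
#' rate of at most `max_error_rate` over the overlap.  Qualities are truncated
#' identically; reads without a match are returned unchanged.
#'
#' @param reads read table (`id`, `sequence`, `quality`).
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter overlap in bases.
#' @param max_error_rate maximum mismatch fraction over the overlap, in
#'   `[0, 0.5)`.
#' @return the read table with truncated `sequence`/`quality` and a logical
#'   `trimmed` column.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L, max_error_rate = 0.1) {
  stopifnot(nchar(adapter) > 0, max_error_rate >= 0, max_error_rate < 0.5,
            min_overlap >= 1L)
  validate_reads(reads)
  reads <- as.data.table(reads)
  keep <- as.integer(trim_positions_cpp(reads$sequence, toupper(adapter),
                                        as.integer(min_overlap), max_error_rate))
  out <- data.table(id = reads$id,
                    sequence = substr(reads$sequence, 1L, keep),
                    quality = substr(reads$quality, 1L, keep),
                    trimmed = keep < nchar(reads$sequence))
  out
}

#' Mean-quality filter
#'
#' A read fails when its mean Phred+33 score is strictly below `threshold`.
#'
#' @param reads read table.
#' @param threshold Phred threshold (default 30).
#' @return logical vector, `TRUE` = pass.
#' @export
quality_filter <- function(reads, threshold = 30) {
  validate_reads(reads)
  mq <- as.numeric(mean_phred_cpp(reads$quality))
  bad <- is.na(mq) & !is.nan(mq)
  if (any(bad)) {
    stop("non-printable quality character in read ", reads$id[which(bad)[1]])
  }
  # empty reads (NaN mean) pass here; the length filter removes them
  ifelse(is.nan(mq), TRUE, mq >= threshold)
}

#' Minimum-length filter
#'
#' @param reads read table (already adapter-trimmed).
#' @param min_length minimum retained insert length; shorter reads are
#'   discarded (default 15, i.e. 14-nt reads go).
#' @return logical vector, `TRUE` = keep.
#' @export
length_filter <- function(reads, min_length = 15L) {
  nchar(reads$sequence) >= min_length
}

#' Preprocess one sample
#'
#' Applies adapter trimming, then the mean-quality filter, then the
#' minimum-length filter, and reports per-sample counters that always satisfy
#' `n_retained + n_discarded_short + n_discarded_low_quality == n_input`.
#'
#' @param fastq path to a FASTQ file, or a read table.
#' @param adapter,min_overlap,max_error_rate see [trim_adapter()].
#' @param quality_threshold mean Phred threshold; `NA` disables the filter
#'   (rates still reported).
#' @param min_length see [length_filter()].
#' @return list with `reads` (clean read table) and `report` (one-row
#'   data.table: `n_input`, `n_adapter_trimmed`, `n_discarded_low_quality`,
#'   `n_discarded_short`, `n_retained`, `mean_low_quality_rate`).
#' @export
preprocess_sample <- function(fastq, adapter = "AGATCGGAAGAGC",
                              min_overlap = 3L, max_error_rate = 0.1,
                              quality_threshold = 30, min_length = 15L) {
  reads <- if (is.character(fastq)) read_fastq(fastq) else as.data.table(fastq)
  n_input <- nrow(reads)
  if (n_input == 0L) {
    return(list(reads = data.table(id = character(0), sequence = character(0),
                                   quality = character(0)),
                report = data.table(n_input = 0L, n_adapter_trimmed = 0L,
                                    n_discarded_low_quality = 0L,
                                    n_discarded_short = 0L, n_retained = 0L,
                                    mean_low_quality_rate = NA_real_)))
  }
  trimmed <- trim_adapter(reads, adapter, min_overlap, max_error_rate)
  q_pass <- quality_filter(trimmed, if (is.na(quality_threshold)) 0 else quality_threshold)
  low_q_rate <- mean(!quality_filter(trimmed, 30))
  after_q <- trimmed[q_pass]
  l_keep <- length_filter(after_q, min_length)
  clean <- after_q[l_keep, c("id", "sequence", "quality")]
  report <- data.table(
    n_input = n_input,
    n_adapter_trimmed = sum(trimmed$trimmed),
    n_discarded_low_quality = sum(!q_pass),
    n_discarded_short = sum(!l_keep),
    n_retained = nrow(clean),
    mean_low_quality_rate = low_q_rate)
  list(reads = clean, report = report)
}
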