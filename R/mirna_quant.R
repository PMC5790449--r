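# Phase 1: precursor alignment, mature-arm assignment, miRNA counting matrix,
# isomiR calling.

#' Align reads to precursor miRNA hairpins
#'
#' Ungapped, forward-strand, all-best-hits alignment with a mismatch cap
#' (default 3).  For every read the minimum achievable mismatch count over all
#' (precursor, offset) placements is found and every placement achieving it is
#' returned.  Reads with more than 10% `N` bases are skipped (reported via the
#' `n_skipped_N` attribute), not errors.
#'
#' @param reads read table (`id`, `sequence`) or named character vector.
#' @param precursors named character vector of precursor sequences.
#' @param max_mismatches maximum substitutions per alignment.
#' @return `data.table` of hits: `read_id`, `precursor`, `offset` (0-based),
#'   `length`, `mismatches`, `score` (= length - mismatches); attribute
#'   `n_skipped_N` carries the skipped-read count.
#' @export
align_to_precursors <- function(reads, precursors, max_mismatches = 3L) {
  stopifnot(length(precursors) > 0)
  if (is.character(reads)) {
    reads <- data.table(id = if (is.null(names(reads)))
      as.character(seq_along(reads)) else names(reads), sequence = unname(reads))
  }
  seqs <- reads$sequence
  n_frac <- nchar(gsub("[^N]", "", seqs)) / pmax(1L, nchar(seqs))
  use <- n_frac <= 0.10
  hits <- align_unique(seqs[use], reads$id[use], precursors,
                       max_mismatches, both_strands = FALSE)
  out <- data.table(read_id = hits$read_id,
                    precursor = names(precursors)[hits$ref],
                    offset = hits$start,
                    length = nchar(seqs)[match(hits$read_id, reads$id)],
                    mismatches = hits$mismatches)
  out$score <- out$length - out$mismatches
  data.table::setattr(out, "n_skipped_N", sum(!use))
  out
}

# dedupe sequences, align the unique set, re-expand to read ids
align_unique <- function(seqs, ids, refs, max_mm, both_strands) {
  if (length(seqs) == 0L) {
    return(data.table(read_id = character(0), ref = integer(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  u <- unique(seqs)
  map <- match(seqs, u)
  h <- as.data.table(align_ungapped_cpp(u, unname(refs),
                                        as.integer(max_mm), both_strands))
  if (nrow(h) == 0L) {
    return(data.table(read_id = character(0), ref = integer(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  idx <- data.table(read_id = ids, useq = map)
  merged <- merge(idx, h, by.x = "useq", by.y = "read",
                  allow.cartesian = TRUE, sort = FALSE)
  merged[, c("read_id", "ref", "start", "strand", "mismatches"), with = FALSE]
}

#' Assign precursor hits to mature arms
#'
#' A hit is assigned to the mature arm whose annotated interval overlaps at
#' least half of the read; among qualifying arms the largest overlap wins,
#' with ties broken 5p before 3p and then lexicographically.  Hits on
#' precursors without a qualifying arm stay unassigned (`NA`).
#'
#' @param hits [align_to_precursors()] output.
#' @param mature_annotations table with `mature`, `precursor`, `start`, `end`
#'   (0-based half-open on the precursor).
#' @return `hits` with columns `mature`, `d5` (read start minus mature start)
#'   and `d3` (read end minus mature end) added; unassigned rows have `NA`.
#' @export
assign_mature <- function(hits, mature_annotations) {
  ma <- as.data.table(mature_annotations)
  if (nrow(hits) == 0L) {
    return(cbind(hits, data.table(mature = character(0), d5 = integer(0),
                                  d3 = integer(0))))
  }
  h <- copy(as.data.table(hits))
  h[, `:=`(hit_row = .I)]
  cand <- merge(h, ma, by = "precursor", allow.cartesian = TRUE, sort = FALSE,
                suffixes = c("", ".m"))
  cand[, overlap := pmax(0L, pmin(end, offset + length) - pmax(start, offset))]
  cand <- cand[overlap * 2L >= length]
  if (nrow(cand)) {
    cand[, arm := ifelse(grepl("-5p$", mature), 0L, 1L)]
    setorder(cand, hit_row, -overlap, arm, mature)
    cand <- cand[!duplicated(hit_row)]
  }
  h[, `:=`(mature = NA_character_, d5 = NA_integer_, d3 = NA_integer_)]
  if (nrow(cand)) {
    h$mature[cand$hit_row] <- cand$mature
    h$d5[cand$hit_row] <- cand$offset - cand$start
    h$d3[cand$hit_row] <- (cand$offset + cand$length) - cand$end
  }
  h$hit_row <- NULL
  h
}

#' Build the miRNA counting matrix (phase 1)
#'
#' Aligns every preprocessed read of every sample against the precursor set,
#' assigns best hits to mature arms, and counts: a read contributes 1 to each
#' distinct mature feature reached through its tied best hits (homologous
#' features therefore receive identical counts).  Reads with no precursor hit
#' (including high-N reads) form the phase-2 pool, preserving the partition
#' `n_aligned + n_unmapped == n_input` per sample.
#'
#' @param reads_list named list (sample id -> clean read table).
#' @param bundle reference bundle (uses `precursors` and `mature`).
#' @param samples sample sheet (`sample_id`, `specimen`, `batch`,
#'   `subject_id`) covering `names(reads_list)`.
#' @param max_mismatches mismatch cap (default 3).
#' @param return_assignments also return the read-level
#'   (`sample_id`, `read_id`, `mature`) table (memory-heavy on big cohorts).
#' @return list: `se` (`SummarizedExperiment`, counts matures x samples),
#'   `unmapped` (named list of read tables), `isomir_detail` (per-sample
#'   variant groups for [call_isomirs()]), `report` (per-sample accounting),
#'   optionally `assignments`.
#' @export
build_mirna_counts <- function(reads_list, bundle, samples,
                               max_mismatches = 3L,
                               return_assignments = FALSE) {
  samples <- as.data.table(samples)
  if (!all(names(reads_list) %in% samples$sample_id)) {
    stop("reads_list contains samples absent from the sample sheet")
  }
  samples <- samples[match(names(reads_list), sample_id)]
  precursors <- bundle$precursors
  ma <- as.data.table(bundle$mature)
  features <- sort(ma$mature)

  # pool unique sequences across samples, align once
  all_seq <- unlist(lapply(reads_list, function(r) r$sequence), use.names = FALSE)
  useq <- unique(all_seq)
  n_frac <- nchar(gsub("[^N]", "", useq)) / pmax(1L, nchar(useq))
  u_ok <- n_frac <= 0.10
  hits_u <- as.data.table(align_ungapped_cpp(useq[u_ok], unname(precursors),
                                             as.integer(max_mismatches), FALSE))
  aligned_u <- rep(FALSE, length(useq))
  assign_u <- NULL
  iso_u <- NULL
  if (nrow(hits_u)) {
    hits_u[, read := which(u_ok)[read]]
    aligned_u[unique(hits_u$read)] <- TRUE
    hu <- data.table(read_id = as.character(hits_u$read),
                     precursor = names(precursors)[hits_u$ref],
                     offset = hits_u$start,
                     length = nchar(useq)[hits_u$read],
                     mismatches = hits_u$mismatches)
    hu <- assign_mature(hu, ma)
    assigned <- hu[!is.na(mature)]
    if (nrow(assigned)) {
      # one representative placement per (unique sequence, mature)
      setorder(assigned, read_id, mature, mismatches, precursor, offset)
      rep_hit <- assigned[!duplicated(paste(read_id, mature))]
      rep_hit[, sig := as.character(mismatch_signature_cpp(
        useq[as.integer(read_id)], unname(precursors),
        match(precursor, names(precursors)), offset))]
      assign_u <- rep_hit[, c("read_id", "mature", "d5", "d3", "mismatches",
                              "sig"), with = FALSE]
      setnames(assign_u, "read_id", "useq_id")
    }
  }

  assigned_useqs <- if (is.null(assign_u)) integer(0) else
    as.integer(unique(assign_u$useq_id))
  counts <- matrix(0L, length(features), length(reads_list),
                   dimnames = list(features, names(reads_list)))
  unmapped <- vector("list", length(reads_list))
  names(unmapped) <- names(reads_list)
  iso_rows <- list()
  asg_rows <- list()
  rep_rows <- list()
  for (j in seq_along(reads_list)) {
    r <- reads_list[[j]]
    uidx <- match(r$sequence, useq)
    is_aligned <- aligned_u[uidx]
    unmapped[[j]] <- r[!is_aligned, ]
    n_assigned_reads <- 0L
    if (!is.null(assign_u)) {
      tab <- data.table(useq_id = as.character(uidx))[, list(n_reads = .N),
                                                      by = "useq_id"]
      sa <- merge(assign_u, tab, by = "useq_id", sort = FALSE)
      if (nrow(sa)) {
        cs <- sa[, list(count = sum(n_reads)), by = "mature"]
        counts[cs$mature, j] <- as.integer(cs$count)
        n_assigned_reads <- length(unique(sa$useq_id))
        iso <- sa[, list(n_reads = sum(n_reads)),
                  by = c("mature", "d5", "d3", "mismatches", "sig")]
        iso[, sample_id := names(reads_list)[j]]
        iso_rows[[length(iso_rows) + 1L]] <- iso
        if (return_assignments) {
          da <- merge(data.table(read_id = r$id, useq_id = as.character(uidx)),
                      assign_u[, c("useq_id", "mature"), with = FALSE],
                      by = "useq_id", sort = FALSE, allow.cartesian = TRUE)
          da[, sample_id := names(reads_list)[j]]
          asg_rows[[length(asg_rows) + 1L]] <- da[, c("sample_id", "read_id",
                                                      "mature"), with = FALSE]
        }
      }
    }
    n_aligned <- sum(is_aligned)
    rep_rows[[j]] <- data.table(
      sample_id = names(reads_list)[j],
      n_input = nrow(r),
      n_aligned = n_aligned,
      n_unmapped = nrow(r) - n_aligned,
      n_aligned_unassigned = n_aligned -
        sum(is_aligned & uidx %in% assigned_useqs),
      alignment_rate = if (nrow(r)) n_aligned / nrow(r) else NA_real_)
  }
  se <- make_count_se(counts, samples)
  out <- list(se = se,
              unmapped = unmapped,
              isomir_detail = if (length(iso_rows)) rbindlist(iso_rows) else
                data.table(mature = character(0), d5 = integer(0),
                           d3 = integer(0), mismatches = integer(0),
                           sig = character(0), n_reads = integer(0),
                           sample_id = character(0)),
              report = rbindlist(rep_rows))
  if (return_assignments) {
    out$assignments <- if (length(asg_rows)) rbindlist(asg_rows) else NULL
  }
  out
}

#' Call isomiRs from phase-1 variant groups
#'
#' Reads are grouped by (mature arm, 5' shift, 3' shift, substitution
#' signature).  Canonical groups (no shift, no mismatch) are excluded, as are
#' groups with shifts beyond +-5 nt or more than `max_mismatches`
#' substitutions.  A group is reported when its median per-sample supporting
#' reads (zero-filled over the samples of a specimen group) is strictly
#' greater than `support_threshold` in at least one specimen.
#'
#' @param isomir_detail `isomir_detail` from [build_mirna_counts()].
#' @param samples sample sheet with `sample_id` and `specimen`.
#' @param support_threshold strict lower bound on the per-specimen median
#'   supporting reads (default 20).
#' @param max_shift maximum |5'|/|3'| shift (default 5).
#' @param max_mismatches maximum substitutions (default 3).
#' @return `data.table`: `mature`, `variant_class` (`5p_shift`, `3p_shift`,
#'   `internal_mismatch`, `combined`), `d5`, `d3`, `n_mismatches`, `sig`,
#'   one `median_<specimen>` column per group, and `max_median`.
#' @export
call_isomirs <- function(isomir_detail, samples, support_threshold = 20,
                         max_shift = 5L, max_mismatches = 3L) {
  samples <- as.data.table(samples)
  det <- as.data.table(isomir_detail)
  specimens <- unique(samples$specimen)
  n_per_group <- table(samples$specimen)
  det <- det[!(d5 == 0L & d3 == 0L & mismatches == 0L)]
  det <- det[abs(d5) <= max_shift & abs(d3) <= max_shift &
               mismatches <= max_mismatches]
  if (nrow(det) == 0L) {
    return(data.table(mature = character(0), variant_class = character(0),
                      d5 = integer(0), d3 = integer(0),
                      n_mismatches = integer(0), sig = character(0),
                      max_median = numeric(0)))
  }
  det <- merge(det, samples[, c("sample_id", "specimen"), with = FALSE],
               by = "sample_id", sort = FALSE)
  med <- det[, {
    res <- lapply(specimens, function(sp) {
      x <- n_reads[specimen == sp]
      x <- c(x, rep(0L, n_per_group[[sp]] - length(x)))
      median(x)
    })
    names(res) <- paste0("median_", specimens)
    res
  }, by = c("mature", "d5", "d3", "mismatches", "sig")]
  med_cols <- paste0("median_", specimens)
  med[, max_median := do.call(pmax, .SD), .SDcols = med_cols]
  out <- med[max_median > support_threshold]
  out[, variant_class := ifelse(
    d5 != 0L & d3 == 0L & mismatches == 0L, "5p_shift", ifelse(
      d5 == 0L & d3 != 0L & mismatches == 0L, "3p_shift", ifelse(
        d5 == 0L & d3 == 0L & mismatches > 0L, "internal_mismatch",
        "combined")))]
  setnames(out, "mismatches", "n_mismatches")
  setorder(out, -max_median)
  out[, c("mature", "variant_class", "d5", "d3", "n_mismatches", "sig",
          med_cols, "max_median"), with = FALSE]
}
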