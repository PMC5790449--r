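# Phase 2: genome alignment of miRNA-unmapped reads, annotation size
# selection, strand-aware assignment, sncRNA counting matrix.

#' Align reads to the toy genome
#'
#' Ungapped all-best-hits alignment on both strands with a mismatch cap
#' (default 2, a desk-scale stand-in for an end-to-end short-read aligner at
#' default stringency).  A minus-strand hit means the reverse complement of
#' the read matches the forward genome sequence over `[start, end)`.
#'
#' @param reads read table (`id`, `sequence`) or named character vector.
#' @param genome named character vector of contig sequences.
#' @param max_mismatches maximum substitutions.
#' @return `data.table`: `read_id`, `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`.
#' @export
align_to_genome <- function(reads, genome, max_mismatches = 2L) {
  stopifnot(length(genome) > 0)
  if (is.character(reads)) {
    reads <- data.table(id = if (is.null(names(reads)))
      as.character(seq_along(reads)) else names(reads), sequence = unname(reads))
  }
  hits <- align_unique(reads$sequence, reads$id, genome,
                       max_mismatches, both_strands = TRUE)
  len <- nchar(reads$sequence)[match(hits$read_id, reads$id)]
  data.table(read_id = hits$read_id,
             contig = names(genome)[hits$ref],
             start = hits$start,
             end = hits$start + len,
             strand = hits$strand,
             mismatches = hits$mismatches)
}

#' Size-select quantifiable sncRNA annotations
#'
#' Keeps GENCODE-class annotations of transcript length at most 70 nt
#' (boundary inclusive) and all DASHR piRNA and tRNA annotations regardless
#' of length; everything else is dropped.
#'
#' @param annotations annotation table with `class`, `source`, `length`.
#' @param max_gencode_length inclusive length cut for GENCODE annotations.
#' @return the retained subset, same columns.
#' @export
select_quantifiable_annotations <- function(annotations,
                                            max_gencode_length = 70L) {
  a <- as.data.table(annotations)
  if (!"length" %in% names(a) || anyNA(a$length)) {
    stop("annotation without a length")
  }
  keep <- (a$source == "GENCODE" & a$length <= max_gencode_length) |
    (a$source == "DASHR" & a$class %in% c("piRNA", "tRNA"))
  a[keep]
}

#' Assign genomic hits to annotations
#'
#' A hit is assigned to every same-strand annotation covering at least
#' `min_overlap_fraction` of the read's aligned bases.  Tied best hits
#' falling in homologous identical-sequence loci therefore each produce an
#' assignment with full weight.
#'
#' @param hits [align_to_genome()] output.
#' @param annotations (size-selected) annotation table.
#' @param min_overlap_fraction minimum covered fraction of the read.
#' @return `data.table` with `read_id` and annotation `id`, one row per
#'   (hit, annotation) assignment.
#' @export
assign_to_annotations <- function(hits, annotations, min_overlap_fraction = 0.9) {
  h <- as.data.table(hits)
  if (nrow(h) == 0L) return(data.table(read_id = character(0), id = character(0)))
  a <- as.data.table(annotations)
  qgr <- GenomicRanges::GRanges(h$contig,
                                IRanges::IRanges(h$start + 1L, h$end),
                                strand = h$strand)
  sgr <- annotations_to_granges(a)
  ov <- GenomicRanges::findOverlaps(qgr, sgr, ignore.strand = FALSE)
  if (length(ov) == 0L) return(data.table(read_id = character(0), id = character(0)))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  inter <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(qgr)[qh], IRanges::ranges(sgr)[sh]))
  keep <- inter >= min_overlap_fraction * IRanges::width(qgr)[qh]
  unique(data.table(read_id = h$read_id[qh[keep]], id = a$id[sh[keep]]))
}

#' Build the non-miRNA sncRNA counting matrix (phase 2)
#'
#' Aligns the phase-1 unmapped pools to the genome, size-selects the
#' annotations, assigns same-strand covering annotations and counts unique
#' (read, annotation) pairs.  Per-sample accounting preserves the partition
#' `assigned + unassigned_mapped + genome_unmapped == pool size`.
#'
#' @param unmapped_list named list (sample id -> phase-2 read table), e.g.
#'   `build_mirna_counts()$unmapped`.
#' @param bundle reference bundle (uses `genome` and `sncrna`).
#' @param samples sample sheet covering the list names.
#' @param max_mismatches genome mismatch cap (default 2).
#' @param min_overlap_fraction see [assign_to_annotations()].
#' @param return_assignments also return read-level assignments.
#' @return list: `se` (counts over quantifiable annotations), `report`
#'   (per-sample pool size, genome alignment and assignment rates),
#'   optionally `assignments`.
#' @export
build_sncrna_counts <- function(unmapped_list, bundle, samples,
                                max_mismatches = 2L,
                                min_overlap_fraction = 0.9,
                                return_assignments = FALSE) {
  samples <- as.data.table(samples)
  samples <- samples[match(names(unmapped_list), sample_id)]
  annot <- select_quantifiable_annotations(bundle$sncrna)
  features <- sort(annot$id)

  all_seq <- unlist(lapply(unmapped_list, function(r) r$sequence),
                    use.names = FALSE)
  useq <- unique(all_seq)
  hits_u <- if (length(useq)) align_unique(useq, as.character(seq_along(useq)),
                                           bundle$genome, max_mismatches,
                                           both_strands = TRUE) else
    data.table(read_id = character(0), ref = integer(0), start = integer(0),
               strand = character(0), mismatches = integer(0))
  mapped_u <- rep(FALSE, length(useq))
  assign_u <- data.table(useq_id = character(0), id = character(0))
  if (nrow(hits_u)) {
    mapped_u[as.integer(unique(hits_u$read_id))] <- TRUE
    gh <- data.table(read_id = hits_u$read_id,
                     contig = names(bundle$genome)[hits_u$ref],
                     start = hits_u$start,
                     end = hits_u$start +
                       nchar(useq)[as.integer(hits_u$read_id)],
                     strand = hits_u$strand,
                     mismatches = hits_u$mismatches)
    assign_u <- assign_to_annotations(gh, annot, min_overlap_fraction)
    setnames(assign_u, "read_id", "useq_id")
  }
  assigned_useqs <- as.integer(unique(assign_u$useq_id))

  counts <- matrix(0L, length(features), length(unmapped_list),
                   dimnames = list(features, names(unmapped_list)))
  rep_rows <- list()
  asg_rows <- list()
  for (j in seq_along(unmapped_list)) {
    r <- unmapped_list[[j]]
    if (nrow(r) == 0L) {
      warning("sample ", names(unmapped_list)[j], " has an empty phase-2 pool")
    }
    uidx <- match(r$sequence, useq)
    is_mapped <- if (nrow(r)) mapped_u[uidx] else logical(0)
    is_assigned <- if (nrow(r)) uidx %in% assigned_useqs else logical(0)
    if (nrow(assign_u)) {
      tab <- data.table(useq_id = as.character(uidx))[, list(n_reads = .N),
                                                      by = "useq_id"]
      sa <- merge(assign_u, tab, by = "useq_id", sort = FALSE)
      if (nrow(sa)) {
        cs <- sa[, list(count = sum(n_reads)), by = "id"]
        counts[cs$id, j] <- as.integer(cs$count)
        if (return_assignments) {
          da <- merge(data.table(read_id = r$id, useq_id = as.character(uidx)),
                      assign_u, by = "useq_id", sort = FALSE,
                      allow.cartesian = TRUE)
          da[, sample_id := names(unmapped_list)[j]]
          asg_rows[[length(asg_rows) + 1L]] <-
            da[, c("sample_id", "read_id", "id"), with = FALSE]
        }
      }
    }
    rep_rows[[j]] <- data.table(
      sample_id = names(unmapped_list)[j],
      n_pool = nrow(r),
      n_genome_aligned = sum(is_mapped),
      n_assigned = sum(is_assigned),
      n_unassigned_mapped = sum(is_mapped & !is_assigned),
      n_genome_unmapped = sum(!is_mapped),
      genome_alignment_rate = if (nrow(r)) sum(is_mapped) / nrow(r) else NA_real_,
      assignment_rate = if (nrow(r)) sum(is_assigned) / nrow(r) else NA_real_)
  }
  out <- list(se = make_count_se(counts, samples), report = rbindlist(rep_rows))
  if (return_assignments) {
    out$assignments <- if (length(asg_rows)) rbindlist(asg_rows) else NULL
  }
  out
}
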