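# Reference-RNA stability: MAD/median ratio ranking per specimen.

#' Rank candidate reference features by MAD/median
#'
#' For each candidate feature, computes the median and the (unscaled) median
#' absolute deviation of its normalized expression over the samples of one
#' specimen group, and ranks candidates by ascending MAD/median ratio.  The
#' consistency constant is deliberately omitted: the ranking is invariant to
#' any positive scaling of the MAD.  Candidates with median 0 are excluded
#' with a warning (their ratio is undefined).  Ties are broken by higher
#' median, then feature id.
#'
#' @param se `SummarizedExperiment` with `normcounts`.
#' @param group specimen label.
#' @param candidates feature ids to rank (typically the specimen-specific
#'   detected set from [venn_partition()]).
#' @return `data.table`: `feature`, `specimen`, `median`, `mad`, `ratio`,
#'   `rank` (1..n, ascending ratio).
#' @export
stability_rank <- function(se, group, candidates) {
  x <- SummarizedExperiment::assay(se, "normcounts")
  idx <- SummarizedExperiment::colData(se)$specimen == group
  if (!any(idx)) stop("empty or unknown group: ", group)
  missing <- setdiff(candidates, rownames(x))
  if (length(missing)) stop("unknown candidate features: ",
                            paste(missing, collapse = ", "))
  sub <- x[candidates, idx, drop = FALSE]
  med <- apply(sub, 1, median)
  madv <- apply(sub, 1, function(v) median(abs(v - median(v))))
  zero <- med == 0
  if (any(zero)) {
    warning("excluding candidates with median 0: ",
            paste(candidates[zero], collapse = ", "))
  }
  out <- data.table(feature = candidates[!zero], specimen = group,
                    median = med[!zero], mad = madv[!zero],
                    ratio = madv[!zero] / med[!zero])
  setorder(out, ratio, -median, feature)
  out[, rank := seq_len(.N)]
  out[]
}

#' Top-k reference candidates per specimen
#'
#' @param records one or more [stability_rank()] tables (rbind-able).
#' @param k rows to keep per specimen (default 10); fewer candidates than
#'   `k` returns all of them with a `note`.
#' @return `data.table` of the top-k records per specimen, ordered by
#'   ascending ratio, with a `note` column.
#' @export
reference_report <- function(records, k = 10L) {
  rec <- as.data.table(records)
  out <- rec[, {
    note <- if (.N < k) sprintf("only %d candidates", .N) else ""
    head(.SD[order(ratio, -median, feature)], k)[, list(
      feature, median, mad, ratio, rank, note = note)]
  }, by = "specimen"]
  out[]
}
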