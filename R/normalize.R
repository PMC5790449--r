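# Library size factors (median-of-ratios), normalization, batch centering.

#' Assemble a counting matrix into a SummarizedExperiment
#'
#' @param counts integer matrix, features x samples.
#' @param samples sample sheet (`sample_id`, `specimen`, `batch`,
#'   `subject_id`) matching the columns.
#' @return a `SummarizedExperiment` with assay `counts`.
#' @export
make_count_se <- function(counts, samples) {
  samples <- as.data.frame(samples)
  stopifnot(identical(colnames(counts), samples$sample_id),
            !anyDuplicated(rownames(counts)), !anyDuplicated(colnames(counts)),
            all(counts >= 0))
  rownames(samples) <- samples$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples))
}

#' Median-of-ratios library size factors
#'
#' For each sample, the factor is the median over features (restricted to
#' rows positive in every sample) of the ratio of that sample's count to the
#' feature's geometric mean across samples.  When no all-positive row exists,
#' total-count scaling (column sum over mean column sum) is used with a
#' warning.
#'
#' @param counts count matrix (features x samples) or a
#'   `SummarizedExperiment` with a `counts` assay.
#' @return positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature with nonzero counts in all samples; ",
            "falling back to total-count scaling")
    cs <- colSums(counts)
    return(cs / mean(cs))
  }
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  # median taken on the ratio scale (not of log ratios): with an even number
  # of features the two conventions differ
  apply(sub, 2, function(col) median(col / geo))
}

#' Normalize a counting matrix by library size factors
#'
#' Divides each column by its size factor.  With `per_group = TRUE`
#' (the default) factors are computed within each specimen group, so that
#' groups with very different library compositions do not distort one
#' another's factors.  The result gains a `normcounts` assay and a
#' `size_factor` column in `colData`.
#'
#' @param se `SummarizedExperiment` with a `counts` assay and a `specimen`
#'   column in `colData`.
#' @param factors optional externally computed factors (named by sample).
#' @param per_group compute factors per specimen group.
#' @return the `SummarizedExperiment` with assay `normcounts` added.
#' @export
normalize_counts <- function(se, factors = NULL, per_group = TRUE) {
  counts <- SummarizedExperiment::assay(se, "counts")
  if (is.null(factors)) {
    if (per_group) {
      specimen <- SummarizedExperiment::colData(se)$specimen
      factors <- rep(NA_real_, ncol(counts))
      names(factors) <- colnames(counts)
      for (sp in unique(specimen)) {
        idx <- which(specimen == sp)
        factors[idx] <- size_factors(counts[, idx, drop = FALSE])
      }
    } else {
      factors <- size_factors(counts)
    }
  }
  if (any(factors <= 0)) stop("size factors must be positive")
  norm <- sweep(counts, 2, factors, "/")
  SummarizedExperiment::assay(se, "normcounts") <- norm
  SummarizedExperiment::colData(se)$size_factor <- unname(factors)
  se
}

#' Remove batch (study) offsets by per-feature median centering
#'
#' Within the corrected specimen group, each feature's `log10(x + 1)` values
#' are shifted so that every batch has the same median: subtract the batch
#' median and add back the grand median over the group, then invert the
#' transform (clamped at zero).  Samples outside `specimen` are untouched.
#' This is a transparent surrogate for latent-factor batch correction: it
#' removes exactly the planted additive log-scale study offsets the cohort
#' generator creates.
#'
#' @param se `SummarizedExperiment` with a `normcounts` assay and `specimen`,
#'   `batch` columns in `colData`.
#' @param specimen the specimen group to correct (default `"plasma"`).
#' @return the `SummarizedExperiment` with `normcounts` corrected and a
#'   `batch_corrected` flag in `metadata`.
#' @export
batch_center <- function(se, specimen = "plasma") {
  cd <- SummarizedExperiment::colData(se)
  idx <- which(cd$specimen == specimen)
  batches <- cd$batch[idx]
  if (length(unique(batches)) < 2L) {
    stop("batch_center needs >= 2 batches within the '", specimen, "' group")
  }
  if (any(table(batches) == 1L)) {
    warning("a batch with a single sample is centered on that one value")
  }
  x <- SummarizedExperiment::assay(se, "normcounts")[, idx, drop = FALSE]
  lx <- log10(x + 1)
  grand <- matrixStats::rowMedians(lx)
  centered <- lx
  for (b in unique(batches)) {
    bi <- which(batches == b)
    bm <- matrixStats::rowMedians(lx[, bi, drop = FALSE])
    centered[, bi] <- lx[, bi, drop = FALSE] - bm + grand
  }
  out <- pmax(10^centered - 1, 0)
  norm <- SummarizedExperiment::assay(se, "normcounts")
  norm[, idx] <- out
  SummarizedExperiment::assay(se, "normcounts") <- norm
  S4Vectors::metadata(se)$batch_corrected <- specimen
  se
}
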