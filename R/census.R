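# Detection census: thresholding, Venn decomposition, top features, PCA,
# paired-subject correlation.

#' Detection census over specimen groups
#'
#' A feature is detected in a specimen group when its median normalized count
#' over the group's samples is strictly greater than `threshold`.
#'
#' @param se `SummarizedExperiment` with a `normcounts` assay and `specimen`
#'   in `colData`.
#' @param threshold strict detection threshold on the group median
#'   (default 20).
#' @return `data.table` with `feature`, one `median_<group>` and one
#'   `detected_<group>` column per specimen group, and `pattern` (sorted
#'   `+`-joined detected groups; `""` when detected nowhere).
#' @export
detect_features <- function(se, threshold = 20) {
  x <- SummarizedExperiment::assay(se, "normcounts")
  specimen <- SummarizedExperiment::colData(se)$specimen
  groups <- unique(specimen)
  if (any(table(specimen) == 0L) || length(groups) == 0L) {
    stop("every specimen group must contain at least one sample")
  }
  med <- vapply(groups, function(g)
    matrixStats::rowMedians(x[, specimen == g, drop = FALSE]),
    numeric(nrow(x)))
  det <- med > threshold
  pattern <- apply(det, 1, function(d) paste(sort(groups[d]), collapse = "+"))
  out <- data.table(feature = rownames(x))
  for (g in groups) out[[paste0("median_", g)]] <- med[, g]
  for (g in groups) out[[paste0("detected_", g)]] <- det[, g]
  out$pattern <- pattern
  data.table::setattr(out, "groups", groups)
  data.table::setattr(out, "threshold", threshold)
  out
}

#' Venn decomposition of a detection table
#'
#' Partitions the features detected somewhere into the cells of the Venn
#' diagram over specimen groups: each feature lands in exactly the cell
#' matching its detection pattern.
#'
#' @param detection a [detect_features()] table.
#' @return list: `cells` (named list, sorted `+`-joined subset -> feature
#'   ids), `counts` (named integer vector over the same cells), `common`
#'   (full-intersection features), `specific` (named list of singleton
#'   cells), `n_detected`, `n_globally_unique`.
#' @export
venn_partition <- function(detection) {
  groups <- attr(detection, "groups")
  if (is.null(groups)) {
    groups <- sub("^detected_", "",
                  grep("^detected_", names(detection), value = TRUE))
  }
  det <- detection[pattern != ""]
  subsets <- unlist(lapply(seq_along(groups), function(k)
    utils::combn(sort(groups), k, paste, collapse = "+")))
  cells <- setNames(lapply(subsets, function(s) det$feature[det$pattern == s]),
                    subsets)
  counts <- vapply(cells, length, 0L)
  singles <- sort(groups)
  list(cells = cells,
       counts = counts,
       common = cells[[paste(sort(groups), collapse = "+")]],
       specific = setNames(lapply(singles, function(g) cells[[g]]), singles),
       n_detected = nrow(det),
       n_globally_unique = sum(counts[singles]))
}

#' Top expressed features of a specimen group
#'
#' @param se `SummarizedExperiment` with `normcounts`.
#' @param group specimen label.
#' @param k number of features to return.
#' @return `data.table` (`feature`, `median`), sorted by descending group
#'   median with lexicographic tie-break.
#' @export
top_expressed <- function(se, group, k = 10L) {
  if (k <= 0) stop("k must be positive")
  x <- SummarizedExperiment::assay(se, "normcounts")
  idx <- SummarizedExperiment::colData(se)$specimen == group
  if (!any(idx)) stop("empty or unknown group: ", group)
  med <- matrixStats::rowMedians(x[, idx, drop = FALSE])
  ord <- order(-med, rownames(x))
  data.table(feature = rownames(x)[ord], median = med[ord])[seq_len(min(k, nrow(x)))]
}

#' PCA embedding of samples
#'
#' Centered (unscaled) principal components of `log10(x + 1)` normalized
#' counts, restricted to features detected in at least one specimen group.
#'
#' @param se `SummarizedExperiment` with `normcounts`.
#' @param detection optional [detect_features()] table used to restrict
#'   features; computed at the default threshold when missing.
#' @param n_components components to keep.
#' @return list: `coordinates` (samples x PCs, with `specimen`), `explained`
#'   (per-PC variance fraction), `sdev`.
#' @export
pca_embed <- function(se, detection = NULL, n_components = 5L) {
  x <- SummarizedExperiment::assay(se, "normcounts")
  if (is.null(detection)) detection <- detect_features(se)
  feats <- detection$feature[detection$pattern != ""]
  lx <- t(log10(x[feats, , drop = FALSE] + 1))
  if (nrow(lx) < 2L || ncol(lx) < 2L) stop("need >= 2 samples and >= 2 features")
  p <- prcomp(lx, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  coords <- as.data.table(p$x[, seq_len(k), drop = FALSE])
  coords[, sample_id := rownames(lx)]
  coords[, specimen := SummarizedExperiment::colData(se)$specimen]
  tot <- sum(p$sdev^2)
  list(coordinates = coords,
       explained = if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev)),
       sdev = p$sdev)
}

#' Paired-subject correlation between two specimens
#'
#' For subjects providing both specimens, computes per-feature Pearson
#' correlation of `log10(x + 1)` normalized counts across the paired samples,
#' with a two-sided t-distribution p-value and a Benjamini-Hochberg column
#' (reported, not used for filtering).  Features constant in either specimen
#' are flagged (`degenerate`) with `NA` correlation.  Only features detected
#' in both specimens are tested.
#'
#' @param se `SummarizedExperiment` with `normcounts` and `specimen`,
#'   `subject_id` in `colData`.
#' @param pair character(2) specimen labels.
#' @param detection optional [detect_features()] table.
#' @return `data.table`: `feature`, `n`, `r`, `p_value`, `p_adjusted`,
#'   `degenerate`.
#' @export
paired_correlation <- function(se, pair, detection = NULL) {
  stopifnot(length(pair) == 2L)
  cd <- SummarizedExperiment::colData(se)
  x <- SummarizedExperiment::assay(se, "normcounts")
  s1 <- which(cd$specimen == pair[1])
  s2 <- which(cd$specimen == pair[2])
  common_subj <- intersect(cd$subject_id[s1], cd$subject_id[s2])
  if (length(common_subj) < 3L) stop("need >= 3 paired subjects")
  i1 <- s1[match(common_subj, cd$subject_id[s1])]
  i2 <- s2[match(common_subj, cd$subject_id[s2])]
  if (is.null(detection)) detection <- detect_features(se)
  d1 <- detection[[paste0("detected_", pair[1])]]
  d2 <- detection[[paste0("detected_", pair[2])]]
  feats <- detection$feature[d1 & d2]
  n <- length(common_subj)
  rows <- lapply(feats, function(f) {
    a <- log10(x[f, i1] + 1); b <- log10(x[f, i2] + 1)
    if (var(a) == 0 || var(b) == 0) {
      return(data.table(feature = f, n = n, r = NA_real_, p_value = NA_real_,
                        degenerate = TRUE))
    }
    r <- cor(a, b)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    data.table(feature = f, n = n, r = r,
               p_value = 2 * pt(-abs(tstat), df = n - 2), degenerate = FALSE)
  })
  out <- rbindlist(rows)
  out[, p_adjusted := p.adjust(p_value, method = "BH")]
  out
}
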