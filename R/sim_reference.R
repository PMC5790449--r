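#' Build the toy reference bundle
#'
#' Generates, deterministically from the config seed, a reference consisting
#' of (i) miRNA precursor hairpins with 5p/3p mature arm annotations
#' (0-based half-open coordinates on the precursor), and (ii) a toy genome
#' whose contigs embed piRNA, tRNA and GENCODE-class sncRNA loci separated by
#' random spacer sequence.  At least one piRNA homolog group (two loci at
#' distinct coordinates with byte-identical sequence) is planted, some loci
#' are placed on the minus strand, and a configurable number of GENCODE-class
#' loci exceed 70 nt so that the downstream size-selection filter has
#' something to exclude.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `reference_bundle` with elements `genome`
#'   (named character), `precursors` (named character), `mature`
#'   (data.table: `mature`, `precursor`, `start`, `end`), `sncrna`
#'   (data.table: `id`, `class`, `source`, `contig`, `start`, `end`,
#'   `strand`, `length`, `sequence`, `homolog_group`) and `mirna_sets`
#'   (the planted miRNA id sets).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  specimens <- config$specimens
  n_specific <- config$n_specific_per_specimen

  mirna_names <- c(
    if (config$n_common_mirnas > 0)
      sprintf("mir-common-%02d", seq_len(config$n_common_mirnas)),
    unlist(lapply(specimens, function(sp) {
      if (n_specific[[sp]] > 0)
        sprintf("mir-%s-%02d", sp, seq_len(n_specific[[sp]]))
    })),
    if (config$n_paired_correlated > 0)
      sprintf("mir-paired-%02d", seq_len(config$n_paired_correlated)),
    if (config$n_background_mirnas > 0)
      sprintf("mir-bg-%02d", seq_len(config$n_background_mirnas)))

  prec_len <- sample(60:90, length(mirna_names), replace = TRUE)
  precursors <- setNames(rand_dna(prec_len), mirna_names)

  # mature arms: 5p near the hairpin 5' end, 3p near the 3' end
  start5 <- sample(5:8, length(mirna_names), replace = TRUE)
  len5 <- sample(21:23, length(mirna_names), replace = TRUE)
  len3 <- sample(21:23, length(mirna_names), replace = TRUE)
  end3 <- prec_len - sample(5:8, length(mirna_names), replace = TRUE)
  mature <- rbind(
    data.table(mature = paste0(mirna_names, "-5p"), precursor = mirna_names,
               start = start5, end = start5 + len5),
    data.table(mature = paste0(mirna_names, "-3p"), precursor = mirna_names,
               start = end3 - len3, end = end3))
  setorder(mature, precursor, start)
  stopifnot(all(mature$end <= prec_len[match(mature$precursor, mirna_names)]),
            all(mature$start >= 0))

  # sncRNA loci: ids, classes, lengths, homolog groups
  n_hom <- config$n_homolog_pairs
  if (config$n_pirna < 2L * n_hom)
    stop("configuration error: n_pirna too small for the requested homolog pairs")
  pirna_ids <- sprintf("piR-%04d", seq_len(config$n_pirna))
  pirna_len <- sample(30:32, config$n_pirna, replace = TRUE)
  hom_group <- rep(NA_character_, config$n_pirna)
  if (n_hom > 0) {
    for (h in seq_len(n_hom)) {
      i1 <- 2L * h - 1L; i2 <- 2L * h
      hom_group[c(i1, i2)] <- sprintf("homolog-%02d", h)
      pirna_len[i2] <- pirna_len[i1]
    }
  }
  trna_ids <- sprintf("tRNA-%02d", seq_len(config$n_trna))
  trna_len <- pmax(60L, pmin(88L, round(rnorm(config$n_trna, 74, 7))))
  gshort_ids <- if (config$n_gencode_short > 0)
    sprintf("snoRNA-short-%02d", seq_len(config$n_gencode_short)) else character(0)
  gshort_len <- sample(55:70, config$n_gencode_short, replace = TRUE)
  glong_ids <- if (config$n_gencode_long > 0)
    sprintf("snoRNA-long-%02d", seq_len(config$n_gencode_long)) else character(0)
  glong_len <- sample(75:90, config$n_gencode_long, replace = TRUE)

  snc <- data.table(
    id = c(pirna_ids, trna_ids, gshort_ids, glong_ids),
    class = c(rep("piRNA", config$n_pirna), rep("tRNA", config$n_trna),
              rep("snoRNA", config$n_gencode_short),
              rep("snoRNA", config$n_gencode_long)),
    source = c(rep("DASHR", config$n_pirna + config$n_trna),
               rep("GENCODE", config$n_gencode_short + config$n_gencode_long)),
    length = as.integer(c(pirna_len, trna_len, gshort_len, glong_len)),
    homolog_group = c(hom_group,
                      rep(NA_character_, config$n_trna +
                            config$n_gencode_short + config$n_gencode_long)))

  # locus sequences; homolog partners copy their group leader
  snc$sequence <- rand_dna(snc$length)
  if (n_hom > 0) {
    for (h in seq_len(n_hom)) {
      idx <- which(snc$homolog_group == sprintf("homolog-%02d", h))
      snc$sequence[idx[2]] <- snc$sequence[idx[1]]
    }
  }

  # lay the loci onto contigs with random spacers; every 5th on minus strand
  n_contigs <- 4L
  snc$contig <- sprintf("chrS%d", rep_len(seq_len(n_contigs), nrow(snc)))
  snc$strand <- ifelse(seq_len(nrow(snc)) %% 5L == 0L, "-", "+")
  genome <- setNames(rep("", n_contigs), sprintf("chrS%d", seq_len(n_contigs)))
  snc$start <- NA_integer_; snc$end <- NA_integer_
  for (ci in seq_len(n_contigs)) {
    contig_name <- sprintf("chrS%d", ci)
    idx <- which(snc$contig == contig_name)
    parts <- character(0)
    pos <- 0L
    for (i in idx) {
      spacer <- rand_dna(sample(40:80, 1L))
      parts <- c(parts, spacer)
      pos <- pos + nchar(spacer)
      emb <- if (snc$strand[i] == "+") snc$sequence[i] else
        as.character(revcomp_cpp(snc$sequence[i]))
      parts <- c(parts, emb)
      snc$start[i] <- pos
      snc$end[i] <- pos + snc$length[i]
      pos <- pos + snc$length[i]
    }
    parts <- c(parts, rand_dna(sample(40:80, 1L)))
    genome[contig_name] <- paste0(parts, collapse = "")
  }

  mirna_sets <- list(
    common = if (config$n_common_mirnas > 0)
      sprintf("mir-common-%02d-5p", seq_len(config$n_common_mirnas)) else character(0),
    specific = setNames(lapply(specimens, function(sp) {
      if (n_specific[[sp]] > 0)
        sprintf("mir-%s-%02d-5p", sp, seq_len(n_specific[[sp]])) else character(0)
    }), specimens),
    stable = setNames(lapply(specimens, function(sp) {
      k <- min(config$n_stable_per_specimen, n_specific[[sp]])
      if (k > 0) sprintf("mir-%s-%02d-5p", sp, seq_len(k)) else character(0)
    }), specimens),
    paired = if (config$n_paired_correlated > 0)
      sprintf("mir-paired-%02d-5p", seq_len(config$n_paired_correlated)) else character(0),
    background = if (config$n_background_mirnas > 0)
      sprintf("mir-bg-%02d-5p", seq_len(config$n_background_mirnas)) else character(0))

  bundle <- list(genome = genome, precursors = precursors, mature = mature,
                 sncrna = snc, mirna_sets = mirna_sets)
  class(bundle) <- "reference_bundle"
  validate_reference(bundle)
  bundle
}

# bundle invariants: mature within precursor, annotation sequences extractable,
# homolog groups identical
validate_reference <- function(bundle) {
  m <- bundle$mature
  plen <- nchar(bundle$precursors)[m$precursor]
  stopifnot(all(m$start >= 0), all(m$end > m$start), all(m$end <= plen))
  s <- bundle$sncrna
  stopifnot(all(s$end > s$start), all(s$length == s$end - s$start))
  extracted <- extract_annotation_seq(bundle$genome, s)
  stopifnot(identical(extracted, s$sequence))
  for (g in unique(stats::na.omit(s$homolog_group))) {
    stopifnot(length(unique(s$sequence[which(s$homolog_group == g)])) == 1L)
  }
  invisible(TRUE)
}

# sense-strand sequence of each annotation from the genome
extract_annotation_seq <- function(genome, annot) {
  fwd <- substr(genome[annot$contig], annot$start + 1L, annot$end)
  ifelse(annot$strand == "-", as.character(revcomp_cpp(fwd)), unname(fwd))
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("sncensus reference bundle\n")
  cat("  precursors:", length(x$precursors), "| mature arms:", nrow(x$mature), "\n")
  cat("  genome:", length(x$genome), "contigs,",
      sum(nchar(x$genome)), "bp | sncRNA loci:", nrow(x$sncrna), "\n")
  invisible(x)
}

#' Write a reference bundle to disk
#'
#' Emits `genome.fa`, `precursors.fa`, `mature.tsv` (0-based half-open),
#' `sncrna.gtf` (1-based closed) and `sncrna.bed` (0-based half-open).
#'
#' @param bundle a [build_reference()] result.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_reference <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             precursors = file.path(dir, "precursors.fa"),
             mature = file.path(dir, "mature.tsv"),
             gtf = file.path(dir, "sncrna.gtf"),
             bed = file.path(dir, "sncrna.bed"))
  write_fasta(bundle$genome, paths[["genome"]])
  write_fasta(bundle$precursors, paths[["precursors"]])
  write_tsv(bundle$mature, paths[["mature"]])
  write_annotations(bundle$sncrna, paths[["gtf"]])
  write_annotations(bundle$sncrna, paths[["bed"]])
  invisible(paths)
}
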