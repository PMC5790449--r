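#' Read a FASTQ file into a read table
#'
#' Reads are returned as a `data.table` with columns `id`, `sequence` and
#' `quality` (Phred+33).  Gzipped files are handled transparently.  Truncated
#' records produce an error naming the offending record index.
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return `data.table` with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record at index %d in '%s'",
                 n_lines %/% 4L + 1L, path), call. = FALSE)
  }
  reads <- tryCatch(
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) {
      stop(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  data.table(
    id = if (is.null(names(reads))) as.character(seq_along(reads)) else names(reads),
    sequence = as.character(reads),
    quality = as.character(Biostrings::quality(reads))
  )
}

#' Write a read table to FASTQ
#'
#' @param reads `data.table`/`data.frame` with `id`, `sequence`, `quality`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  # Biostrings warns about dropping the quality mcols it attaches itself
  withCallingHandlers(
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$quality),
                                compress = grepl("\\.gz$", path)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read/write FASTA sequence sets
#'
#' Thin adapters around Biostrings returning/accepting named character
#' vectors so the rest of the package can stay string-based.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta`: named character vector; `write_fasta`: `path`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# internal: annotation data.frame (0-based half-open) <-> GRanges (1-based closed)
annotations_to_granges <- function(annot) {
  gr <- GenomicRanges::GRanges(
    seqnames = annot$contig,
    ranges = IRanges::IRanges(start = annot$start + 1L, end = annot$end),
    strand = annot$strand)
  S4Vectors::mcols(gr)$ID <- annot$id
  S4Vectors::mcols(gr)$class <- annot$class
  S4Vectors::mcols(gr)$source_db <- annot$source
  gr
}

granges_to_annotations <- function(gr) {
  m <- S4Vectors::mcols(gr)
  data.table(
    id = as.character(m$ID),
    class = as.character(m$class),
    source = as.character(m$source_db),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = GenomicRanges::width(gr))
}

#' Export/import sncRNA annotations as GTF or BED6
#'
#' Internal coordinates are 0-based half-open; GTF is written 1-based closed
#' and BED6 0-based half-open, with the conversion happening only here.
#' GTF attributes carry the annotation class and source database.
#'
#' @param annot annotation table (`id`, `class`, `source`, `contig`, `start`,
#'   `end`, `strand`, `length`).
#' @param path output file; extension selects the format (`.gtf` or `.bed`).
#' @return `path` (export) or an annotation `data.table` (import).
#' @export
write_annotations <- function(annot, path) {
  gr <- annotations_to_granges(annot)
  fmt <- tolower(tools::file_ext(path))
  if (fmt == "gtf") {
    S4Vectors::mcols(gr)$type <- "exon"
    S4Vectors::mcols(gr)$gene_id <- annot$id
    rtracklayer::export(gr, path, format = "gtf")
  } else if (fmt == "bed") {
    names(gr) <- annot$id
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  } else {
    stop("unsupported annotation format: ", fmt)
  }
  invisible(path)
}

#' @rdname write_annotations
#' @param class_lookup optional named vectors used to restore `class`/`source`
#'   columns when importing BED (which carries no attributes).
#' @export
read_annotations <- function(path, class_lookup = NULL) {
  fmt <- tolower(tools::file_ext(path))
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gtf") {
    m <- S4Vectors::mcols(gr)
    out <- data.table(
      id = as.character(m$gene_id),
      class = as.character(m$class),
      source = as.character(m$source_db),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      length = GenomicRanges::width(gr))
  } else {
    out <- data.table(
      id = as.character(gr$name),
      class = if (is.null(class_lookup)) NA_character_ else unname(class_lookup$class[as.character(gr$name)]),
      source = if (is.null(class_lookup)) NA_character_ else unname(class_lookup$source[as.character(gr$name)]),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      length = GenomicRanges::width(gr))
  }
  out
}

#' Read/write tab-separated tables
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv`: a `data.table`; `write_tsv`: `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) data.table::fread(path, sep = "\t")

validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("id", "sequence", "quality") %in% names(reads)))
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad)) {
    stop(sprintf("read %s: sequence and quality lengths differ", reads$id[bad[1]]))
  }
  invisible(TRUE)
}
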