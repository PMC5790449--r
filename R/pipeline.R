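# End-to-end pipeline: simulate (optional) -> preprocess -> phase-1 miRNA
# quantification -> phase-2 sncRNA quantification -> normalization and batch
# centering -> census -> stability -> classification, with TSV/JSON artifacts
# and a machine-readable run manifest.

#' Run the full small RNA census pipeline
#'
#' Executes every stage on either a freshly simulated cohort (when `config`
#' is a [simulation_config()]) or on existing FASTQ files (`fastq_dir` plus
#' `sample_sheet` and a reference written by [write_reference()]).  Each
#' stage writes its artifacts under `out_dir` and contributes read-count
#' accounting to `manifest.json`; a stage failure halts the run with the
#' stage name while earlier artifacts remain on disk.
#'
#' @param out_dir output directory.
#' @param config [simulation_config()] driving the synthetic cohort (ignored
#'   when `fastq_dir` is given).
#' @param fastq_dir optional directory of `<sample>.fastq` files.
#' @param sample_sheet optional sample sheet path/table (required with
#'   `fastq_dir`).
#' @param reference_dir optional directory from [write_reference()]
#'   (required with `fastq_dir`).
#' @param threshold detection threshold (default 20).
#' @param max_mismatches,max_genome_mismatches mismatch caps of the two
#'   phases.
#' @param isomir_support isomiR support threshold (default 20).
#' @param batch_method `"median-center"` (default) or `"none"`.
#' @param classify_folds,classify_trees cross-validation parameters.
#' @param top_k rows in the reference report.
#' @return invisibly, a list of all stage results (`bundle`, `truth`,
#'   `mirna`, `sncrna`, `detection`, `venn`, `stability`, `classifier`, ...).
#' @export
run_pipeline <- function(out_dir,
                         config = simulation_config(),
                         fastq_dir = NULL, sample_sheet = NULL,
                         reference_dir = NULL,
                         threshold = 20,
                         max_mismatches = 3L, max_genome_mismatches = 2L,
                         isomir_support = 20,
                         batch_method = c("median-center", "none"),
                         classify_folds = 10L, classify_trees = 500L,
                         top_k = 10L) {
  batch_method <- match.arg(batch_method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "sncensus",
                   version = as.character(utils::packageVersion("sncensus")),
                   parameters = list(threshold = threshold,
                                     max_mismatches = max_mismatches,
                                     max_genome_mismatches = max_genome_mismatches,
                                     isomir_support = isomir_support,
                                     batch_method = batch_method,
                                     classify_folds = classify_folds,
                                     classify_trees = classify_trees),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.null(fastq_dir)) {
    manifest$seed <- config$seed
    sim <- stage("simulate", {
      simulate_cohort(config, file.path(out_dir, "reads"))
    })
    bundle <- sim$bundle
    truth <- sim$truth
    samples <- sim$samples
    fastq <- sim$fastq
    write_reference(bundle, file.path(out_dir, "reference"))
    adapter <- config$adapter
  } else {
    if (is.null(sample_sheet) || is.null(reference_dir)) {
      stop("fastq_dir requires sample_sheet and reference_dir")
    }
    samples <- if (is.character(sample_sheet)) read_tsv(sample_sheet) else
      as.data.table(sample_sheet)
    fastq <- setNames(file.path(fastq_dir, paste0(samples$sample_id, ".fastq")),
                      samples$sample_id)
    missing_fq <- !file.exists(fastq)
    if (any(missing_fq)) {
      stop("missing FASTQ for samples: ",
           paste(samples$sample_id[missing_fq], collapse = ", "))
    }
    bundle <- stage("load-reference", load_reference(reference_dir))
    truth <- NULL
    adapter <- config$adapter
  }

  pp <- stage("preprocess", {
    res <- lapply(fastq, preprocess_sample, adapter = adapter)
    reads <- lapply(res, `[[`, "reads")
    report <- rbindlist(lapply(res, `[[`, "report"))
    report[, sample_id := names(res)]
    write_tsv(report, file.path(out_dir, "preprocess_report.tsv"))
    list(reads = reads, report = report)
  })
  manifest$stages$preprocess <- accounting(pp$report$n_retained)

  m <- stage("quant-mirna", {
    res <- build_mirna_counts(pp$reads, bundle, samples,
                              max_mismatches = max_mismatches)
    write_matrix_tsv(SummarizedExperiment::assay(res$se, "counts"),
                     file.path(out_dir, "mirna_counts.tsv"))
    write_tsv(res$report, file.path(out_dir, "mirna_alignment_report.tsv"))
    res
  })
  manifest$stages$mirna_aligned <- accounting(m$report$n_aligned)

  s <- stage("quant-sncrna", {
    res <- build_sncrna_counts(m$unmapped, bundle, samples,
                               max_mismatches = max_genome_mismatches)
    write_matrix_tsv(SummarizedExperiment::assay(res$se, "counts"),
                     file.path(out_dir, "sncrna_counts.tsv"))
    write_tsv(res$report, file.path(out_dir, "sncrna_alignment_report.tsv"))
    res
  })
  manifest$stages$genome_aligned <- accounting(s$report$n_genome_aligned)
  manifest$stages$sncrna_assigned <- accounting(s$report$n_assigned)

  norm <- stage("normalize", {
    mirna_se <- normalize_counts(m$se)
    sncrna_se <- normalize_counts(s$se)
    can_batch <- batch_method == "median-center" &&
      "plasma" %in% samples$specimen &&
      length(unique(samples$batch[samples$specimen == "plasma"])) >= 2L
    if (can_batch) {
      mirna_se <- batch_center(mirna_se)
      sncrna_se <- batch_center(sncrna_se)
    }
    write_matrix_tsv(SummarizedExperiment::assay(mirna_se, "normcounts"),
                     file.path(out_dir, "mirna_normcounts.tsv"))
    write_matrix_tsv(SummarizedExperiment::assay(sncrna_se, "normcounts"),
                     file.path(out_dir, "sncrna_normcounts.tsv"))
    list(mirna = mirna_se, sncrna = sncrna_se, batch_corrected = can_batch)
  })
  manifest$stages$batch_corrected <- norm$batch_corrected

  cen <- stage("census", {
    det_mi <- detect_features(norm$mirna, threshold)
    det_snc <- detect_features(norm$sncrna, threshold)
    venn_mi <- venn_partition(det_mi)
    venn_snc <- venn_partition(det_snc)
    write_tsv(det_mi, file.path(out_dir, "mirna_detection.tsv"))
    write_tsv(det_snc, file.path(out_dir, "sncrna_detection.tsv"))
    jsonlite::write_json(list(mirna = as.list(venn_mi$counts),
                              sncrna = as.list(venn_snc$counts)),
                         file.path(out_dir, "venn_counts.json"),
                         auto_unbox = TRUE)
    list(det_mi = det_mi, det_snc = det_snc,
         venn_mi = venn_mi, venn_snc = venn_snc)
  })

  iso <- stage("isomir", {
    calls <- call_isomirs(m$isomir_detail, samples,
                          support_threshold = isomir_support)
    write_tsv(calls, file.path(out_dir, "isomirs.tsv"))
    calls
  })

  stab <- stage("stability", {
    recs <- list()
    for (sp in unique(samples$specimen)) {
      cand_mi <- cen$venn_mi$specific[[sp]]
      cand_snc <- cen$venn_snc$specific[[sp]]
      if (length(cand_mi) > 0) {
        recs[[paste0(sp, "_mirna")]] <- stability_rank(norm$mirna, sp, cand_mi)
      }
      if (length(cand_snc) > 0) {
        recs[[paste0(sp, "_sncrna")]] <- stability_rank(norm$sncrna, sp, cand_snc)
      }
    }
    mi_recs <- recs[grep("_mirna$", names(recs))]
    empty_rec <- data.table(specimen = character(0), feature = character(0),
                            median = numeric(0), mad = numeric(0),
                            ratio = numeric(0), rank = integer(0),
                            note = character(0))
    write_tsv(if (length(mi_recs)) reference_report(rbindlist(mi_recs), k = top_k)
              else empty_rec,
              file.path(out_dir, "reference_mirnas.tsv"))
    snc_recs <- recs[grep("_sncrna$", names(recs))]
    write_tsv(if (length(snc_recs)) reference_report(rbindlist(snc_recs), k = top_k)
              else empty_rec,
              file.path(out_dir, "reference_sncrnas.tsv"))
    recs
  })

  cls <- stage("classify", {
    rep <- train_evaluate(norm$mirna, seed = if (is.null(truth)) 1L else config$seed,
                          folds = classify_folds, trees = classify_trees,
                          detection = cen$det_mi)
    merit <- chi_square_merit(norm$mirna, detection = cen$det_mi)
    jsonlite::write_json(list(accuracy = rep$accuracy,
                              n_misclassified = rep$n_misclassified,
                              scheme = rep$scheme, seed = rep$seed,
                              confusion = as.data.frame(rep$confusion)),
                         file.path(out_dir, "classifier_report.json"),
                         auto_unbox = TRUE)
    write_tsv(merit, file.path(out_dir, "chi_square_merit.tsv"))
    list(report = rep, merit = merit)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(bundle = bundle, truth = truth, samples = samples,
                 preprocess = pp, mirna = m, sncrna = s, normalized = norm,
                 detection = cen, isomirs = iso, stability = stab,
                 classifier = cls, manifest = manifest))
}

accounting <- function(x) {
  list(mean = mean(x), min = min(x), max = max(x), total = sum(x))
}

write_matrix_tsv <- function(m, path) {
  dt <- data.table(feature = rownames(m))
  dt <- cbind(dt, as.data.table(m))
  write_tsv(dt, path)
}

#' Load a reference bundle written by [write_reference()]
#'
#' @param dir the reference directory.
#' @return a `reference_bundle`.
#' @export
load_reference <- function(dir) {
  snc <- read_annotations(file.path(dir, "sncrna.gtf"))
  genome <- read_fasta(file.path(dir, "genome.fa"))
  snc$sequence <- extract_annotation_seq(genome, snc)
  # homolog groups are re-derived from sequence identity
  snc$homolog_group <- NA_character_
  dup <- snc$sequence[duplicated(snc$sequence)]
  for (i in seq_along(unique(dup))) {
    snc$homolog_group[snc$sequence == unique(dup)[i]] <- sprintf("homolog-%02d", i)
  }
  bundle <- list(genome = genome,
                 precursors = read_fasta(file.path(dir, "precursors.fa")),
                 mature = read_tsv(file.path(dir, "mature.tsv")),
                 sncrna = snc,
                 mirna_sets = NULL)
  class(bundle) <- "reference_bundle"
  bundle
}

#' Minimal command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `run-all` (simulate
#' and run every stage).  Flags: `--out DIR`, `--seed N`, `--depth N`,
#' `--threshold X`, `--adapter SEQ`, `--trees N`, `--folds N`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
sncensus_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: sncensus <simulate|run-all> --out DIR [--seed N] ",
            "[--depth N] [--threshold X] [--adapter SEQ] [--trees N] [--folds N]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list(out = "sncensus_out", seed = 1L, depth = 50000L,
               threshold = 20, adapter = "AGATCGGAAGAGC",
               trees = 500L, folds = 10L)
  flags <- args[-1]
  i <- 1L
  while (i < length(flags)) {
    key <- sub("^--", "", flags[i])
    if (!key %in% names(opts)) stop("unknown flag: ", flags[i])
    opts[[key]] <- utils::type.convert(flags[i + 1L], as.is = TRUE)
    i <- i + 2L
  }
  config <- simulation_config(seed = as.integer(opts$seed),
                              depth = as.integer(opts$depth),
                              adapter = opts$adapter)
  if (cmd == "simulate") {
    simulate_cohort(config, opts$out)
  } else if (cmd == "run-all") {
    run_pipeline(opts$out, config, threshold = opts$threshold,
                 classify_folds = as.integer(opts$folds),
                 classify_trees = as.integer(opts$trees))
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
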