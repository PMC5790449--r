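# Cohort simulation: planted expression units, true counts, read synthesis.
#
# An "expression unit" is the thing reads are drawn from: a mature miRNA arm,
# an sncRNA locus (a homologous identical-sequence piRNA group is a single
# unit whose reads hit all member loci), or the unmappable "microbiome" pool.

# unit table + base relative-abundance matrix (units x specimens)
plant_units <- function(config, bundle) {
  sets <- bundle$mirna_sets
  snc <- bundle$sncrna
  specimens <- config$specimens

  # sncRNA units: collapse homolog groups to their group id
  snc_unit_id <- ifelse(is.na(snc$homolog_group), snc$id, snc$homolog_group)
  snc_units <- data.table(unit = snc_unit_id, locus = snc$id,
                          class = snc$class, source = snc$source,
                          length = snc$length)
  snc_units <- snc_units[, list(loci = paste(locus, collapse = ","),
                                class = class[1], source = source[1],
                                length = length[1]), by = "unit"]

  pirna_units <- snc_units$unit[snc_units$class == "piRNA"]
  trna_units <- snc_units$unit[snc_units$class == "tRNA"]
  gshort_units <- snc_units$unit[snc_units$source == "GENCODE" & snc_units$length <= 70]
  glong_units <- snc_units$unit[snc_units$source == "GENCODE" & snc_units$length > 70]

  take <- function(x, n) head(x, n)
  snc_common <- c(take(pirna_units, 4L), take(trna_units, 4L), gshort_units)
  rest_pirna <- setdiff(pirna_units, snc_common)
  rest_trna <- setdiff(trna_units, snc_common)
  snc_specific <- setNames(vector("list", length(specimens)), specimens)
  for (sp in specimens) {
    if (sp == "cervical") { snc_specific[[sp]] <- character(0); next }
    n_pi <- min(2L, length(rest_pirna))
    picks <- take(rest_pirna, n_pi)
    rest_pirna <- setdiff(rest_pirna, picks)
    if (sp == "urine") {
      n_tr <- min(2L, length(rest_trna))
      tr <- take(rest_trna, n_tr)
      rest_trna <- setdiff(rest_trna, tr)
      picks <- c(picks, tr)
    }
    snc_specific[[sp]] <- picks
  }
  snc_background <- setdiff(snc_units$unit, c(snc_common, unlist(snc_specific)))

  units <- rbind(
    data.table(unit = c(sets$common, unlist(unname(sets$specific)), sets$paired,
                        sets$background),
               family = "mirna", class = "miRNA", source = "miRBase",
               loci = NA_character_),
    data.table(unit = snc_units$unit, family = "sncrna",
               class = snc_units$class, source = snc_units$source,
               loci = snc_units$loci))

  # base relative abundances (normalized later); margins are wide so that the
  # detection threshold (median normalized reads > 20) is met or missed with
  # room to spare at the default depth of 50k reads/sample
  w <- matrix(0, nrow(units), length(specimens),
              dimnames = list(units$unit, specimens))
  w[sets$common, ] <- 0.008
  for (sp in specimens) {
    w[sets$specific[[sp]], sp] <- 0.010
    if (length(snc_specific[[sp]])) w[snc_specific[[sp]], sp] <- 0.012
  }
  if (length(sets$paired)) w[sets$paired, config$paired_specimens] <- 0.010
  if (length(sets$background)) w[sets$background, ] <- 3e-5
  w[snc_common, ] <- 0.012
  if (length(snc_background)) w[snc_background, ] <- 5e-5
  if (length(glong_units)) w[glong_units, ] <- 0.004

  # user-supplied profiles override the planted ones per specimen
  if (!is.null(config$specimen_profiles)) {
    for (sp in names(config$specimen_profiles)) {
      prof <- config$specimen_profiles[[sp]]
      unknown <- setdiff(names(prof), units$unit)
      if (length(unknown))
        stop("specimen_profiles refers to features absent from the reference: ",
             paste(unknown, collapse = ", "))
      w[, sp] <- 0
      w[names(prof), sp] <- prof
    }
  }

  # per-unit log10 dispersion: stable candidates are narrow
  sigma <- rep(config$sigma_log10, nrow(units))
  names(sigma) <- units$unit
  stable_units <- unlist(unname(sets$stable))
  snc_stable <- vapply(snc_specific, function(x)
    if (length(x)) x[1] else NA_character_, "")
  snc_stable <- snc_stable[!is.na(snc_stable)]
  sigma[c(stable_units, unname(snc_stable))] <- config$sigma_stable

  units$sigma <- sigma
  units$batch_responsive <- seq_len(nrow(units)) %% 2L == 1L
  list(units = units,
       weights = w,
       sets = list(mirna = sets,
                   snc_common = snc_common,
                   snc_specific = snc_specific,
                   snc_background = snc_background,
                   snc_stable = as.list(snc_stable),
                   excluded_by_size = glong_units))
}

# sample sheet: ids, specimen, batch (plasma split over three studies),
# subject pairing across specimens
build_sample_sheet <- function(config) {
  rows <- lapply(config$specimens, function(sp) {
    n <- config$n_samples_per_specimen[[sp]]
    batch <- switch(sp,
      plasma = sprintf("study%d", ((seq_len(n) - 1L) %% 3L) + 1L),
      stool = rep("study1", n),
      urine = rep("study2", n),
      rep(paste0("batch_", sp), n))
    subject <- if (sp %in% c("plasma", "stool", "urine"))
      sprintf("subj_%03d", seq_len(n))
    else sprintf("subj_%s_%03d", sp, seq_len(n))
    data.table(sample_id = sprintf("%s_%02d", sp, seq_len(n)),
               specimen = sp, batch = batch, subject_id = subject)
  })
  rbindlist(rows)
}

#' Simulate true per-feature counts for a cohort
#'
#' Draws, for every sample, a multinomial vector of reads-per-expression-unit
#' from the specimen's planted relative-abundance profile.  Per-sample
#' biological variation is logistic-normal: each unit's weight is multiplied
#' by `10^(sigma * N(0,1))` and the profile renormalized (planted stable
#' features use a much smaller sigma).  Paired-correlated features share a
#' subject-level latent factor between the two paired specimens so that their
#' log10 expression correlates at the target rho.  Batch log10 offsets are
#' applied to the batch-responsive half of the units in samples whose batch
#' appears in `batch_log_offsets`.  Column sums equal `depth` exactly.
#'
#' @param config a [simulation_config()].
#' @param bundle a [build_reference()] result for the same config.
#' @return an object of class `ground_truth`: `counts` (units x samples
#'   integer matrix, including the `microbiome` row), `samples` (sample
#'   sheet), `units`, and `sets` (planted feature id sets).
#' @export
simulate_true_counts <- function(config, bundle) {
  stopifnot(inherits(config, "sim_config"), inherits(bundle, "reference_bundle"))
  set.seed(config$seed + 1L)
  planted <- plant_units(config, bundle)
  units <- planted$units
  samples <- build_sample_sheet(config)

  paired_units <- planted$sets$mirna$paired
  subjects <- unique(samples$subject_id)
  z_subj <- matrix(rnorm(length(subjects) * length(paired_units)),
                   nrow = length(subjects),
                   dimnames = list(subjects, paired_units))

  counts <- matrix(0L, nrow(units) + 1L, nrow(samples),
                   dimnames = list(c(units$unit, "microbiome"),
                                   samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    sp <- samples$specimen[j]
    w <- planted$weights[, sp]
    jitter <- 10^(units$sigma * rnorm(nrow(units)))
    w <- w * jitter
    if (length(paired_units) && sp %in% config$paired_specimens) {
      eps <- rnorm(length(paired_units))
      z <- sqrt(config$rho) * z_subj[samples$subject_id[j], paired_units] +
        sqrt(1 - config$rho) * eps
      w[paired_units] <- planted$weights[paired_units, sp] *
        10^(config$tau_paired * z)
    }
    off <- config$batch_log_offsets[samples$batch[j]]
    if (!is.na(off) && off != 0) {
      w[units$batch_responsive] <- w[units$batch_responsive] * 10^off
    }
    frac_mic <- config$microbiome_fraction[sp]
    if (is.na(frac_mic)) frac_mic <- 0
    prob <- c(w / sum(w) * (1 - frac_mic), frac_mic)
    counts[, j] <- rmultinom(1, config$depth, prob)[, 1]
  }

  truth <- list(counts = counts, samples = samples, units = units,
                sets = planted$sets, weights = planted$weights)
  class(truth) <- "ground_truth"
  truth
}

#' Expand unit-level true counts to locus-level rows
#'
#' Homologous identical-sequence piRNA loci each receive the full count of
#' their unit (consistent with the shared counting rule of the quantifier);
#' other units map one-to-one.
#'
#' @param truth a [simulate_true_counts()] result.
#' @return integer matrix, loci (and mature miRNA ids) x samples.
#' @export
truth_locus_counts <- function(truth) {
  units <- truth$units
  rows <- lapply(seq_len(nrow(units)), function(i) {
    loci <- if (is.na(units$loci[i])) units$unit[i] else
      strsplit(units$loci[i], ",", fixed = TRUE)[[1]]
    m <- matrix(rep(truth$counts[units$unit[i], ], length(loci)),
                nrow = length(loci), byrow = TRUE,
                dimnames = list(loci, colnames(truth$counts)))
    m
  })
  do.call(rbind, rows)
}

#' Synthesize FASTQ reads for a simulated cohort
#'
#' Every true count becomes one read: a biological insert (mature miRNA
#' sequence, an sncRNA locus fragment of 30--70 nt, or 40 nt of random
#' "microbiome" sequence), followed by the 3' adapter and 10 random padding
#' bases.  A configurable fraction of miRNA reads are emitted as isomiR
#' variants with a 1 nt shift at the 5' or 3' end.  Substitution errors
#' at `insert_error_rate` are applied to the insert.  Most reads carry
#' constant Q37 qualities; a `low_quality_fraction` gets Q20 so the mean-Q<30
#' filter has work to do.  Read ids encode sample, source unit and isomiR
#' shifts (`sample|unit|serial|d5|d3`) so downstream assignment accuracy is
#' exactly computable.
#'
#' @param config,bundle,truth as produced by the companion functions.
#' @param out_dir output directory; one `<sample>.fastq` per sample plus
#'   `samples.tsv` and `truth_counts.tsv`.
#' @return list with `fastq` (named paths), `samples`, `truth`.
#' @export
synthesize_reads <- function(config, bundle, truth, out_dir) {
  set.seed(config$seed + 2L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  units <- truth$units
  mat <- bundle$mature
  prec <- bundle$precursors
  mat5 <- mat[match(units$unit, mat$mature), ]
  snc_seq <- setNames(bundle$sncrna$sequence, bundle$sncrna$id)
  unit_seq <- ifelse(units$family == "mirna",
                     substr(prec[mat5$precursor], mat5$start + 1L, mat5$end),
                     snc_seq[vapply(strsplit(units$loci, ","), `[`, "", 1L)])
  prec_len <- setNames(nchar(prec), names(prec))

  # single-nucleotide templated shifts: the dominant isomiR classes
  iso_shifts <- rbind(
    data.table(d5 = c(-1L, 1L), d3 = 0L),
    data.table(d5 = 0L, d3 = c(-1L, 1L)))

  fastq_paths <- setNames(file.path(out_dir, paste0(truth$samples$sample_id, ".fastq")),
                          truth$samples$sample_id)
  for (j in seq_len(nrow(truth$samples))) {
    sid <- truth$samples$sample_id[j]
    cnt <- truth$counts[, j]
    ins <- character(0); src <- character(0)
    d5v <- integer(0); d3v <- integer(0)
    for (i in seq_len(nrow(units))) {
      n <- cnt[units$unit[i]]
      if (n == 0L) next
      if (units$family[i] == "mirna") {
        s0 <- mat5$start[i]; e0 <- mat5$end[i]
        pl <- prec_len[mat5$precursor[i]]
        d5 <- integer(n); d3 <- integer(n)
        n_iso <- rbinom(1L, n, config$isomir_fraction)
        if (n_iso > 0L) {
          pick <- iso_shifts[sample(nrow(iso_shifts), n_iso, replace = TRUE), ]
          ok <- s0 + pick$d5 >= 0L & e0 + pick$d3 <= pl &
            (e0 + pick$d3) - (s0 + pick$d5) >= 16L
          pick <- pick[ok, ]
          if (nrow(pick)) {
            d5[seq_len(nrow(pick))] <- pick$d5
            d3[seq_len(nrow(pick))] <- pick$d3
          }
        }
        seqs <- substr(rep(prec[[mat5$precursor[i]]], n), s0 + d5 + 1L, e0 + d3)
        ins <- c(ins, seqs); d5v <- c(d5v, d5); d3v <- c(d3v, d3)
      } else if (units$family[i] == "sncrna") {
        full <- unit_seq[i]; len <- nchar(full)
        if (len <= 36L) {
          seqs <- rep(full, n); }
        else {
          L <- sample(30:min(70L, len), n, replace = TRUE)
          s <- vapply(len - L, function(m) sample.int(m + 1L, 1L) - 1L, 1L)
          seqs <- substr(rep(full, n), s + 1L, s + L)
        }
        ins <- c(ins, seqs); d5v <- c(d5v, integer(n)); d3v <- c(d3v, integer(n))
      } else {
        ins <- c(ins, rand_dna(rep(40L, n)))
        d5v <- c(d5v, integer(n)); d3v <- c(d3v, integer(n))
      }
      src <- c(src, rep(units$unit[i], n))
    }
    n_mic <- cnt[["microbiome"]]
    if (n_mic > 0L) {
      ins <- c(ins, rand_dna(rep(40L, n_mic)))
      src <- c(src, rep("microbiome", n_mic))
      d5v <- c(d5v, integer(n_mic)); d3v <- c(d3v, integer(n_mic))
    }
    ins <- as.character(mutate_bases_cpp(ins, config$insert_error_rate))
    pad <- rand_dna(rep(10L, length(ins)))
    seqs <- paste0(ins, config$adapter, pad)
    qual <- strrep("F", nchar(seqs))
    low <- runif(length(seqs)) < config$low_quality_fraction
    qual[low] <- strrep("5", nchar(seqs[low]))
    ids <- sprintf("%s|%s|%06d|%d|%d", sid, src, seq_along(src), d5v, d3v)
    perm <- sample(length(ids))
    write_fastq(data.table(id = ids[perm], sequence = seqs[perm],
                           quality = qual[perm]),
                fastq_paths[[sid]])
  }
  write_tsv(truth$samples, file.path(out_dir, "samples.tsv"))
  tc <- data.table(feature = rownames(truth$counts))
  tc <- cbind(tc, as.data.table(truth$counts))
  write_tsv(tc, file.path(out_dir, "truth_counts.tsv"))
  list(fastq = fastq_paths, samples = truth$samples, truth = truth)
}

#' Simulate a full cohort (reference + counts + reads)
#'
#' Convenience wrapper: [build_reference()], [simulate_true_counts()] and
#' [synthesize_reads()] under one seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir directory for FASTQ files, sample sheet and truth tables.
#' @param bundle optional pre-built reference bundle.
#' @return list with `bundle`, `truth`, `fastq`, `samples`.
#' @export
simulate_cohort <- function(config, out_dir, bundle = NULL) {
  if (is.null(bundle)) bundle <- build_reference(config)
  truth <- simulate_true_counts(config, bundle)
  reads <- synthesize_reads(config, bundle, truth, out_dir)
  list(bundle = bundle, truth = truth, fastq = reads$fastq,
       samples = reads$samples)
}

#' Expand expression-unit ids to locus ids
#'
#' Maps planted unit ids (where a homologous piRNA group is a single unit) to
#' the annotation locus ids appearing as rows of the phase-2 counting matrix.
#'
#' @param truth a [simulate_true_counts()] result.
#' @param ids unit ids.
#' @return character vector of locus ids.
#' @export
expand_unit_ids <- function(truth, ids) {
  u <- truth$units
  unlist(lapply(ids, function(i) {
    j <- match(i, u$unit)
    if (is.na(j) || is.na(u$loci[j])) i else
      strsplit(u$loci[j], ",", fixed = TRUE)[[1]]
  }), use.names = FALSE)
}

#' Decode read provenance from simulated read ids
#'
#' @param ids character vector of read ids from [synthesize_reads()].
#' @return `data.table` with `sample_id`, `unit`, `d5`, `d3`.
#' @export
truth_from_ids <- function(ids) {
  parts <- data.table::tstrsplit(ids, "|", fixed = TRUE)
  data.table(sample_id = parts[[1]], unit = parts[[2]],
             d5 = as.integer(parts[[4]]), d3 = as.integer(parts[[5]]))
}
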