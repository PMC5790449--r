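#' Configuration for the synthetic small RNA cohort
#'
#' Describes a toy reference and a multi-specimen, multi-batch sequencing
#' cohort with planted ground truth: miRNAs shared by every specimen, miRNAs
#' detected in exactly one specimen, a low-dispersion (candidate reference)
#' miRNA per specimen, features whose expression is correlated between paired
#' specimens of the same subject, study-specific batch offsets for plasma, and
#' a configurable unmappable ("microbiome") read fraction for stool.
#'
#' Defaults emulate the cohort structure the package's census analysis
#' assumes: four specimen groups (plasma exosomes, stool, urine, cervical
#' scrapes) with the plasma group split over three studies, eleven common
#' miRNAs, specimen-specific sets of sizes 8/5/3/1, and paired
#' plasma--urine/stool subjects.
#'
#' @param seed integer seed; the same seed reproduces the cohort byte for
#'   byte (FASTA, GTF, FASTQ, sample sheet, truth tables).
#' @param n_samples_per_specimen named integer vector, samples per specimen
#'   group; names define the specimen labels.
#' @param depth reads per sample.
#' @param adapter 3' adapter sequence appended to every insert.
#' @param insert_error_rate per-base substitution probability applied to the
#'   biological insert.
#' @param n_common_mirnas number of miRNAs expressed above the detection
#'   threshold in every specimen.
#' @param n_specific_per_specimen named integer vector: miRNAs expressed in
#'   exactly one specimen.  The first member of each set is the planted
#'   low-dispersion "reference" candidate.
#' @param n_stable_per_specimen low-dispersion features per specimen (taken
#'   from the head of the specimen-specific set).
#' @param n_paired_correlated features with subject-level correlated
#'   expression between the specimens in `paired_specimens`.
#' @param rho target Pearson correlation of paired features (log scale).
#' @param paired_specimens character(2): the specimen pair sharing the
#'   correlated latent factor (subject-matched).
#' @param batch_log_offsets named numeric vector of log10 expression offsets
#'   per batch, applied to the batch-responsive half of the features.
#' @param n_background_mirnas miRNAs expressed below the detection threshold
#'   everywhere.
#' @param n_pirna,n_trna,n_gencode_short,n_gencode_long sncRNA locus counts in
#'   the toy annotation (piRNA ~31 nt, tRNA ~74 nt, GENCODE-class loci of
#'   length <= 70 and > 70 respectively).
#' @param n_homolog_pairs piRNA homolog groups (two loci, identical sequence).
#' @param isomir_fraction fraction of miRNA reads emitted as 5'/3' shifted
#'   isomiR variants.
#' @param low_quality_fraction fraction of reads with mean Phred below 30.
#' @param microbiome_fraction named numeric vector: per-specimen fraction of
#'   reads drawn as random unmappable sequence.
#' @param sigma_log10 per-sample log10 biological dispersion of ordinary
#'   features.
#' @param sigma_stable log10 dispersion of the planted stable features.
#' @param tau_paired log10 scale of the subject-level latent factor driving
#'   paired-feature correlation.
#' @param n_precursors optional cap on the number of miRNA precursors in the
#'   reference; it is an error to request more planted miRNAs than this.
#' @param specimen_profiles optional list of named numeric vectors (feature ->
#'   relative abundance) overriding the automatically planted profiles; all
#'   ids must exist in the reference.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_samples_per_specimen = c(plasma = 12L, stool = 12L, urine = 12L, cervical = 12L),
    depth = 50000L,
    adapter = "AGATCGGAAGAGC",
    insert_error_rate = 0.005,
    n_common_mirnas = 11L,
    n_specific_per_specimen = c(plasma = 8L, stool = 5L, urine = 3L, cervical = 1L),
    n_stable_per_specimen = 1L,
    n_paired_correlated = 2L,
    rho = 0.6,
    paired_specimens = c("plasma", "urine"),
    batch_log_offsets = c(study1 = 0, study2 = 0.3, study3 = -0.3),
    n_background_mirnas = 30L,
    n_pirna = 20L,
    n_trna = 10L,
    n_gencode_short = 5L,
    n_gencode_long = 5L,
    n_homolog_pairs = 1L,
    isomir_fraction = 0.15,
    low_quality_fraction = 0.02,
    microbiome_fraction = c(stool = 0.2),
    sigma_log10 = 0.25,
    sigma_stable = 0.03,
    tau_paired = 0.4,
    n_precursors = NULL,
    specimen_profiles = NULL) {
  specimens <- names(n_samples_per_specimen)
  if (is.null(specimens) || anyDuplicated(specimens))
    stop("n_samples_per_specimen must have unique names")
  n_specific_per_specimen <-
    n_specific_per_specimen[intersect(names(n_specific_per_specimen), specimens)]
  missing_spec <- setdiff(specimens, names(n_specific_per_specimen))
  if (length(missing_spec)) {
    n_specific_per_specimen[missing_spec] <- 0L
  }
  if (depth <= 0) stop("depth must be positive")
  if (insert_error_rate < 0 || insert_error_rate > 1)
    stop("insert_error_rate must be in [0, 1]")
  microbiome_fraction <-
    microbiome_fraction[names(microbiome_fraction) %in% specimens]
  if (n_paired_correlated > 0 && !all(paired_specimens %in% specimens)) {
    # paired features degrade gracefully to unpaired when the pair is absent
    n_paired_correlated <- 0L
  }
  n_mirna_needed <- n_common_mirnas + sum(n_specific_per_specimen) +
    n_paired_correlated + n_background_mirnas
  if (!is.null(n_precursors) && n_precursors < n_mirna_needed) {
    stop(sprintf(
      "configuration error: %d planted miRNA precursors requested but n_precursors = %d",
      n_mirna_needed, n_precursors))
  }
  if (n_stable_per_specimen > 0 &&
      any(n_specific_per_specimen < pmin(n_stable_per_specimen,
                                         n_specific_per_specimen) * 0L)) {
    stop("n_stable_per_specimen exceeds a specimen-specific set")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_samples_per_specimen = n_samples_per_specimen,
    specimens = specimens,
    depth = as.integer(depth),
    adapter = toupper(adapter),
    insert_error_rate = insert_error_rate,
    n_common_mirnas = as.integer(n_common_mirnas),
    n_specific_per_specimen = n_specific_per_specimen,
    n_stable_per_specimen = as.integer(n_stable_per_specimen),
    n_paired_correlated = as.integer(n_paired_correlated),
    rho = rho,
    paired_specimens = paired_specimens,
    batch_log_offsets = batch_log_offsets,
    n_background_mirnas = as.integer(n_background_mirnas),
    n_pirna = as.integer(n_pirna),
    n_trna = as.integer(n_trna),
    n_gencode_short = as.integer(n_gencode_short),
    n_gencode_long = as.integer(n_gencode_long),
    n_homolog_pairs = as.integer(n_homolog_pairs),
    isomir_fraction = isomir_fraction,
    low_quality_fraction = low_quality_fraction,
    microbiome_fraction = microbiome_fraction,
    sigma_log10 = sigma_log10,
    sigma_stable = sigma_stable,
    tau_paired = tau_paired,
    n_precursors = n_precursors,
    specimen_profiles = specimen_profiles)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sncensus simulation config\n")
  cat("  specimens:", paste(sprintf("%s(%d)", x$specimens,
                                    x$n_samples_per_specimen), collapse = " "), "\n")
  cat("  depth:", x$depth, "reads/sample; seed:", x$seed, "\n")
  cat("  planted miRNAs: common", x$n_common_mirnas, "| specific",
      paste(x$n_specific_per_specimen, collapse = "/"),
      "| paired", x$n_paired_correlated, "(rho", x$rho, ")\n")
  invisible(x)
}

# deterministic random DNA: one vector per call, split by lengths
rand_dna <- function(lengths) {
  if (length(lengths) == 0L) return(character(0))
  total <- sum(lengths)
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  grp <- rep.int(seq_along(lengths), lengths)
  vapply(split(chars, grp), paste0, collapse = "", FUN.VALUE = "")
}
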