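---
title: "sncensus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sncensus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Biofluids and other easily collected specimens — plasma-derived exosomes,
stool, urine, cervical scrapes — carry distinct populations of small
non-coding RNAs (miRNAs, piRNAs, tRNAs and other short species). Two
questions recur in biomarker work on such material: *which* small RNAs are
reliably detectable in which specimen, and *which* of them are stable enough
across subjects to serve as endogenous reference genes for RT-qPCR
validation. `sncensus` implements a complete desk-scale pipeline for both
questions, driven by a synthetic cohort generator with planted ground truth
so that every stage can be tested against known answers.

# The two-phase quantification model

**Phase 1 (miRNome).** Adapter-trimmed reads are aligned, ungapped and on the
forward strand, against precursor miRNA hairpins. For every read we find the
minimum achievable substitution count over all (precursor, offset) placements
and keep *all* placements achieving it, subject to a cap of 3 mismatches.
Each hit is assigned to the mature arm (5p/3p) whose annotated interval
covers at least half of the read, largest overlap winning and ties broken 5p
first. A read contributes a count of 1 to every distinct mature feature
reached through its tied best hits; this "full weight to all tied features"
policy is forced by the homolog rule of phase 2 (below) and means column
sums can exceed aligned-read counts, which the per-sample report states
separately. Reads with no precursor placement form the phase-2 pool, so
`aligned + unmapped = input` exactly, per sample.

**Phase 2 (other sncRNAs).** The phase-1 leftovers are aligned to the genome
on both strands (cap 2 mismatches, an approximation of an end-to-end
short-read aligner at default stringency). Annotations are *size-selected*
first: GENCODE-class records are kept only up to 70 nt (inclusive), while
DASHR piRNA and tRNA records are kept regardless of length — tRNAs average
74±7 nt and would otherwise vanish from the census. A genomic hit is
assigned to every same-strand annotation covering at least 90% of the read's
aligned bases. Homologous piRNA loci with identical sequence therefore tie
for every read that touches one of them, and their counting-matrix rows are
*exactly* equal in every sample — an invariant the tests assert rather than
a statistical tendency.

Both aligners live in `src/align.cpp` for speed and are verified against an
exhaustive position-by-position R oracle on hundreds of random instances.

# Normalization and batch structure

Library size factors are median-of-ratios: factor~j~ = median over
all-positive features *i* of count~ij~ / geomean~i~. Two numerical points
worth knowing:

* the median is taken on the **ratio scale**. Taking it on the log scale
  (geometric mean of the two middle ratios) differs whenever the number of
  usable features is even; the brute-force oracle in the test suite caught
  exactly this.
* size factors are identifiable only up to a global constant: multiplying a
  single column by *c* rescales its factor by c^(1-1/n)^ and all others by
  c^(-1/n)^, so normalized matrices agree up to the common factor c^(1/n)^.
  The test asserts that exact form rather than the idealized "only its own
  factor changes".

Factors are computed per specimen group by default, since groups with very
different RNA composition (stool vs urine) should not distort one another.

Multi-study plasma groups carry systematic study offsets. Instead of a
latent-factor method, `batch_center()` performs per-feature per-batch median
centering on the `log10(x+1)` scale (subtract the batch median, add back the
grand median, invert, clamp at zero). This removes exactly the additive
log-scale offsets the generator plants, is an identity when batches are
identically distributed, leaves non-plasma columns byte-identical, and is
fully auditable — the reasons it was preferred over an off-the-shelf
surrogate-variable analysis here.

# Census, stability, classification

A feature is *detected* in a specimen when its median normalized count over
the group's samples is **strictly** greater than 20 (the boundary median of
exactly 20 is not detected). Detection patterns induce a Venn partition:
the full-intersection cell is the "common" set, singleton cells are
"specimen-specific", and their union is the globally unique set.

Candidate reference RNAs are ranked within each specimen by MAD/median of
normalized expression, ascending; the MAD is the plain
median(|x − median(x)|) without the 1.4826 consistency constant (the ranking
is invariant to any constant). Candidates are the specimen-specific detected
features, ranked separately for miRNAs and non-miRNA sncRNAs; candidates
with median 0 are excluded with a warning. Ties break by higher median, then
feature id.

Specimen classification uses a self-contained random forest (bagged CART,
gini splits, `floor(sqrt(p))` features per node, 500 trees) evaluated by
stratified 10-fold cross-validation on `log10(x+1)` counts of the detected
features — no forest package exists in the supported environment, and the
~50-sample problems here need nothing heavier. Attribute merit is the
chi-square statistic of an equal-frequency-bin × class contingency table;
bins are assigned by rank (ties share a bin), which makes the statistic
exactly invariant under strictly monotone transforms.

Paired-subject correlation between two specimens is the per-feature Pearson
r of `log10(x+1)` normalized counts across subjects providing both
specimens, with a two-sided t p-value; a Benjamini–Hochberg column is
reported but never used for filtering. Features constant in either specimen
are flagged degenerate rather than given an r.

# What the synthetic cohort emulates

`simulation_config()` describes the world; defaults are the conditions the
downstream analysis assumes:

| knob | default | meaning |
|---|---|---|
| specimens × samples | plasma/stool/urine/cervical × 12 | four groups, plasma split over studies 1–3 |
| depth | 50,000 reads/sample | desk-scale library |
| common miRNAs | 11 | above threshold in all four groups |
| specific miRNAs | 8/5/3/1 | above threshold in exactly one group |
| stable feature | first of each specific set | log10 dispersion 0.03 vs 0.25 |
| paired features | 2, ρ = 0.6 | subject-level latent shared plasma↔urine |
| batch offsets | 0/+0.3/−0.3 log10 | study offsets on alternating features |
| adapter | `AGATCGGAAGAGC` | clipped 3' adapter motif |
| insert error rate | 0.005/base | substitutions on the insert |
| isomiR fraction | 0.15 | ±1 nt templated 5'/3' shifts |
| low-quality reads | 2% | mean Q20, removed by the Q<30 filter |
| stool microbiome | 20% | random unmappable sequence |

Design choices a maintainer should know:

* **Biological variation is logistic-normal**, not Dirichlet: each unit's
  weight is multiplied by 10^(σ·N(0,1))^ and the profile renormalized. This
  is the same narrowed-concentration idea with a per-feature dispersion knob
  and lets the paired-feature construction hit its target correlation
  analytically (log counts ≈ const + τ·latent, so Pearson r ≈ ρ).
* **Batch offsets act on alternating features.** A whole-sample multiplier
  is mathematically a size factor and would be invisible after
  normalization; only feature-differential offsets are observable, and the
  deterministic alternating rule keeps the planted structure auditable.
* **Read ids encode provenance** (`sample|unit|serial|d5|d3`), so
  per-read assignment accuracy against ground truth is computed exactly, not
  estimated.
* True counts are multinomial at exactly `depth`, so conservation identities
  are exact, not approximate.

What the generator does **not** emulate: indels and quality decay along the
read, UMI structure, non-templated additions, real microbiome composition
(stool contamination is plain random sequence), cross-mapping between
paralogous miRNA families, and the long-tailed abundance distributions of
real libraries. A green census-recovery test therefore establishes that the
pipeline's logic is correct on data satisfying its assumptions — it does not
establish performance on real libraries, whose difficulty lives exactly in
the features listed above.

# Numerical and boundary conventions

* Internal coordinates are 0-based half-open everywhere; GTF (1-based
  closed) and BED (0-based half-open) conversion happens only in the I/O
  adapters.
* Detection and isomiR support use strict `>` at 20; length filtering keeps
  reads of exactly 15 nt (a 14 vs 15 ambiguity in the underlying protocol
  descriptions was resolved to the stricter observed behaviour, and the
  threshold is a parameter).
* The mean-quality filter passes empty reads (their mean is undefined);
  the length filter removes them one step later.
* Adapter matching requires ≥3 bases of overlap at ≤10% mismatches, taking
  the *leftmost* qualifying position; trimming is therefore not idempotent
  on arbitrary output (a trim can expose a new 3-base suffix match), only on
  genuinely adapter-free sets.
* Reads with >10% `N` are skipped and counted, not errors; `N` mismatches
  every base during alignment.
* PCA is centered, unscaled `prcomp` on log counts of detected features;
  coordinates are deterministic up to component sign.
* All randomness flows from a single integer seed; identical configs
  reproduce FASTA/GTF/FASTQ outputs byte for byte.

# Known limitations

* The aligners are exhaustive scanners — ideal at toy-genome scale and for
  oracle testing, unsuitable for a real hg38.
* Homologous loci are kept as distinct counting rows with enforced equality;
  collapsing them to one feature is a defensible alternative we did not take.
* The isomiR grouping (mature, Δ5', Δ3', substitution signature) is a
  documented approximation of dedicated isomiR callers' windowing rules.
* The batch-centering surrogate removes additive log-scale offsets only; it
  cannot absorb latent factors that are not batch-aligned.
* The chi-square merit uses unsupervised equal-frequency binning, a
  simplification of supervised discretization.
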