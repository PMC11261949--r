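---
title: "Classifying homologous recombination deficiency from six mutational-context features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying homologous recombination deficiency from six mutational-context features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdsix)
```

## The problem

Breast and ovarian tumours that have lost double-strand-break repair by
homologous recombination (HRD tumours) respond to PARP inhibitors and
platinum chemotherapy, while proficient (HRP) tumours do not.  HRD leaves a
characteristic footprint in the somatic mutation catalogue: an excess of
C>G substitutions in NpCpT trinucleotide contexts, deletions of five or
more base pairs flanked by microhomology (the scar of microhomology-mediated
end joining), mid-sized segments with loss of heterozygosity, and amplified
heterozygous segments of 10--40 Mb.  Proficient tumours, conversely, are
dominated by C>T transitions at CpG sites (the clock-like deamination
signal) and by very large, copy-number-quiet heterozygous segments.

`hrdsix` turns this contrast into a classifier.  It works identically for
whole-genome (WGS) and whole-exome (WES) inputs, which matters because
rearrangement-based HRD callers cannot be applied to exomes.

## Context classification

Every somatic event is first assigned to a canonical channel:

* **SBS-96** -- substitutions referenced to the pyrimidine strand, six
  substitution types by sixteen flanking-base contexts.  A purine-reference
  mutation is reverse-complemented before assignment, so a mutation and its
  reverse-complement presentation always share a channel.
* **ID-83** -- indels by length, by C/T base and homopolymer length for
  1 bp events, by the number of adjacent copies of the motif for longer
  events at repeats, and by microhomology length for deletions of 2 bp or
  more that are not at repeats.  The VCF anchor base is stripped before any
  length or homology computation, because classification operates on the
  inserted/deleted sequence itself.  A deletion whose flank contains a full
  adjacent copy of the deleted sequence is a repeat-mediated deletion and
  is never assigned a microhomology channel; the two channel families are
  mutually exclusive.
* **CN-48** -- allele-specific copy-number segments by zygosity (homozygous
  deletion; LOH, i.e. minor copy number 0; heterozygous), total copy
  number (TCN) bin, and segment-size bin.

Size-bin edges are half-open on the upper side: "10--40Mb" means more than
10 Mb and at most 40 Mb.  The field's schema listings do not state edge
inclusivity, so the package fixes one convention and uses it identically in
classification and in feature aggregation; what matters is consistency, not
the particular choice.  Segment size is `end - start + 1` on 1-based
inclusive coordinates.  Sex chromosomes are not treated specially: all
provided segments are classified, and callers can pre-filter if they wish.

Subclonal (fractional) ASCAT copy numbers are not supported: the reader
rejects such rows into its parse report rather than rounding them, because
every downstream rule (LOH, TCN bins) is defined on integer states.

## The enrichment screen

For each channel the screen compares HRD and HRP samples two ways:

* **Effect size** -- the log2 ratio of the group means of per-sample channel
  proportions, with a pseudocount of 1e-6 added to each mean.  The
  pseudocount is needed for determinacy when a channel is absent from one
  group; at 1e-6 it is far below any proportion a real cohort can produce.
* **Significance** -- a two-sided Fisher exact test.  Fisher's test needs a
  contingency table, not a difference of means, so the package pools event
  counts across the samples of each group into the 2x2 table
  (channel vs all-other-channels) x (HRD vs HRP).  Group-mean proportions
  drive only the fold-change axis.

P-values are Benjamini-Hochberg adjusted within each variant class (96, 83
and 48 channels separately), matching the per-class volcano panels the
screen reproduces.  A channel is called enriched when its absolute log2
fold change exceeds the threshold (0.75 for WGS, 0.25 for WES -- exome
catalogues are sparser, so effect sizes are attenuated) **and**
`-log10(q) > 3`.

## The six features

Channels found enriched aggregate into six per-sample features:

| feature | definition | convention |
|---|---|---|
| `loh_1_40mb` | segments with minor CN 0, TCN >= 1, size in (1, 40] Mb | proportion of all segments |
| `del5_mh` | deletions >= 5 bp at microhomologies (`5:Del:M:1-5`) | proportion of indels (WGS), count (WES) |
| `het_3_9_10_40mb` | heterozygous segments, TCN in [3, 9], size in (10, 40] Mb | proportion of all segments |
| `ncgt` | `N[C>G]T` substitutions | proportion of substitutions |
| `nctg` | `N[C>T]G` substitutions | proportion of substitutions |
| `het_2_4_gt40mb` | heterozygous segments, TCN in [2, 4], size > 40 Mb | proportion of all segments |

Three conventions deserve comment.  First, the copy-number features filter
on each segment's **raw** TCN and size, not on its binned CN-48 channel:
the feature definition names TCN 3--9, while the schema bin is "9+", and
filtering on raw values honours the stated range.  Second, `del5_mh` is a
count for exomes and a proportion for genomes.  The only explicit statement
of the count convention concerns exome training, so the package defaults to
proportion for WGS with `del5_as_count` exposed for the alternative.
Third, the LOH feature aggregates across all TCN >= 1 states; the source
description ("multiple significant LOH events") does not restrict TCN, so
the default is inclusive.  Zero denominators (a sample with no events of a
class) yield a feature value of 0 with a warning rather than NA, so a
sparse exome sample still receives a prediction.

## Ground truth and the model

Training labels come from orthogonal genomic evidence: a sample is HRD when
its HRD scar score (the LOH/TAI/LST genomic-instability sum, consumed here
as a number) reaches 42 for breast or 63 for ovarian tumours -- both
thresholds inclusive -- **or** when it carries a germline/somatic BRCA1/2
alteration.  A missing score without BRCA evidence is an error, not HRP:
absence of evidence must not silently produce a proficient label.

The classifier is a linear-kernel support vector machine (hinge loss, L2
penalty) on z-score standardized features:

1. `feature_scaler()` learns per-feature mean and SD on training data only;
   test data always reuses training parameters.  A constant feature falls
   back to SD 1 (standardizing to 0) with a warning.
2. Stratified 10-fold cross-validation selects the regularization strength
   from `c_grid = {0.01, 0.1, 1, 10, 100}` by mean held-out AUC.  The grid,
   the AUC criterion, and the stratified fold draw (controlled by `seed`)
   are this package's choices -- the procedure they implement only fixes
   "10-fold CV for hyper-parameters and feature weights" -- and all are
   exposed as arguments.  Inside each fold the scaler is refit on that
   fold's training part, so no information leaks from held-out samples.
3. The per-fold weight vectors at the selected strength are recorded;
   their mean is the **reported** weight vector (`feature_weights()`,
   `tidy()`), matching the convention of presenting average CV weights.
   Positive weights mark HRD-predictive features (`loh_1_40mb`, `del5_mh`,
   `het_3_9_10_40mb`, `ncgt`), negative weights HRP-predictive ones
   (`nctg`, `het_2_4_gt40mb`).
4. Probabilities come from a Platt-style logistic calibration fitted on the
   out-of-fold decision values (the calibration method is unspecified in
   the source procedure; out-of-fold Platt scaling is fixed here for
   reproducibility), and the final decision function is refit on all
   training data.  A sample is called HRD when its probability is **at
   least** 0.50 -- the threshold is inclusive.

Everything downstream of the seed is deterministic: identical seeds give
bit-identical models, and the model serializes to versioned JSON.

## Down-sampling genomes to exomes

`downsample_mutations()` keeps a mutation when any base of its reference
span overlaps an exome target interval.  `downsample_segments()` keeps a
segment when it overlaps at least one target, **retaining the original
span and copy numbers**.  Clipping segments to exon boundaries would make
the 10--40 Mb and >40 Mb size bins unreachable, which is inconsistent with
exome copy-number features using those bins; the exome determines which
segments are observable, not their recorded extent.  A `clip` flag provides
the alternative reading.  Down-sampling is idempotent and monotone in the
interval set, and both properties are tested.

## The synthetic cohort generator

The generator exists so that every stage -- classification, screen,
features, model, down-sampling -- can be exercised end to end with no data
access.  Its defaults define the study conditions the test-suite and the
acceptance script run under:

* 50 samples per arm; Poisson burdens with means 600 substitutions, 150
  indels and 80 copy-number segments per sample.  These are toy-scale
  stand-ins (a breast genome carries thousands of substitutions); they keep
  a 100-sample cohort under half a minute while leaving per-sample
  proportion estimates stable.
* HRD samples put 25% of substitution mass on the `N[C>G]T` channels and
  5% on `N[C>T]G`; HRP samples mirror this.  30% versus 3% of indel mass
  goes to `5:Del:M:1-5`.  Segment-type mixtures are
  HRD (LOH 1-40 Mb 0.35, HET 3-9 10-40 Mb 0.20, HET 2-4 >40 Mb 0.05,
  other 0.40) and HRP (0.08, 0.04, 0.45, 0.43).  These contrasts (3-9x)
  were chosen once so that the WGS volcano thresholds flag exactly the
  planted channel groups at 50 samples per arm, with the remaining mass
  spread evenly so no other channel differs between arms.
* The toy genome has three chromosomes with a nominal length of 120 Mb.
  Sequence is realized for a 400 kb window per chromosome, and mutations
  are placed there; copy-number segments are drawn across the full nominal
  span, which carries no sequence because segment classification depends
  only on coordinates and copy numbers.  Realizing 360 Mb of random
  sequence would buy nothing: no rule ever reads sequence under a segment.
* Every simulated substitution is placed at a reference position whose
  trinucleotide matches the sampled channel; deletions are drawn from
  pools of reference loci whose re-classification provably yields the
  target channel (candidates proposed by vectorized scans, every candidate
  verified with the classifier itself); insertion alleles are constructed
  and verified the same way.  The generator therefore edits nothing, and
  generator/classifier closure -- every event lands in its intended
  channel -- is exact and tested.
* The exome covers 10% of the nominal genome as 1 kb targets on a regular
  grid.  A real capture design covers 1-2% in ~150 bp exons; at toy
  burdens that would leave too few retained mutations for stable
  proportions, so the toy exome is deliberately denser.  Because the grid
  spacing is 10 kb, every multi-megabase segment overlaps targets, which is
  also true of real exomes.
* Each sample draws from its own RNG substream derived from the master
  seed, so cohorts are reproducible and insensitive to generation order.

What the generator does **not** emulate: mutational-signature mixtures
beyond the planted channels, clonal structure and subclonal copy number,
GC/replication-timing covariates of mutation density, segment boundaries
shared across a genome (segments may overlap), and sequencing noise.
Passing tests therefore demonstrate that the pipeline's logic is correct
and self-consistent under its stated assumptions -- not that the classifier
will reach any particular accuracy on real tumours, which depends on
effect sizes the generator fixes by construction.

`simulate_feature_cohort()` skips catalogue generation entirely and draws
the six features from beta distributions (precision ~60, the stability of
a proportion estimated from ~60 events) with class means matching the
catalogue generator's expectations, and Poisson counts for the exome
`del5_mh` convention.  It is used where only model behaviour is under
study, e.g. permutation-null checks.

## Numerical choices and degenerate inputs

* AUC is the Mann-Whitney rank statistic with ties counted half; a
  single-class truth set yields `NA` with a warning, as do precision and
  sensitivity with empty denominators (never silent zeros).
* Fisher tests use `stats::fisher.test`; the test-suite checks every
  p-value of the screen against an independent hypergeometric tail-sum to
  1e-10.
* The 0.50 call threshold is inclusive; the boundary is tested by
  constructing a sample whose calibrated probability is exactly 0.5.
* Multi-nucleotide substitutions and complex indels classify as `OTHER`
  and are excluded from every matrix, but counted in the exclusion report;
  parsers never silently drop rows (records + report = data rows).
* Mixed chromosome naming is normalised by stripping any `chr` prefix at
  every read boundary.

## Problem sizes

The test-suite runs its unit checks on a 12-sample cohort (six per arm,
~170 events per sample) and its end-to-end checks at the study conditions:
50 samples per arm for the enrichment screen (with a dedicated 3x-contrast
configuration), 200 samples for model recovery with a 20-permutation null,
and the full simulate/train/predict chain twice for byte-identity.  The
acceptance script simulates 100 training and 50 held-out samples at the
default conditions, screens 227 channels, trains WGS and down-sampled-WES
models, and reports recovery, AUC, sensitivity/precision/F1, weight-sign
agreement and WGS/dWES call concordance.  These sizes were chosen as the
smallest at which the planted effects are unambiguous.

## Known limitations

* The CN-48 schema here covers the zygosity/TCN/size dimensions the
  features need; extensions (e.g. transcription-strand or clustered-event
  annotations) are out of scope.
* HRD scar scores are consumed, never computed: deriving LOH/TAI/LST from
  segments is a separate concern.
* The package ships no pre-trained clinical models; training requires a
  labelled cohort.  The synthetic generator is a development harness, not
  a substitute for clinical validation.
* Subclonal copy number, indels with non-ACGT alleles, and symbolic VCF
  ALT records are rejected (visibly, via parse/exclusion reports).
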