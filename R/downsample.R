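# Down-sampling a whole-genome catalogue to whole-exome resolution:
# mutations are kept when any base of their reference span falls inside an
# exome target interval; copy-number segments are kept when they overlap at
# least one target interval, retaining their original genomic span and
# copy numbers (the size bins of downstream classification are computed on
# the original span, as clipped exonic fragments could never reach the
# multi-megabase bins the features use).

#' Down-sample mutations to exome resolution
#'
#' @param mutations Mutation table ([mutation_records()]).
#' @param exome A non-empty [genomic_intervals()] set of exome targets.
#' @return The retained subset of `mutations` (for indels, any overlap of
#'   the reference-allele span counts).
#' @export
downsample_mutations <- function(mutations, exome) {
  stopifnot(inherits(exome, "genomic_intervals"))
  if (nrow(mutations) == 0) return(mutations)
  ref_end <- mutations$pos + nchar(mutations$ref) - 1
  keep <- overlaps_intervals(mutations$chrom, mutations$pos, ref_end, exome)
  mutations[keep, ]
}

#' Down-sample copy-number segments to exome resolution
#'
#' @param segments Segment table ([segment_records()]).
#' @param exome A non-empty [genomic_intervals()] set of exome targets.
#' @param clip If `TRUE`, clip retained segments to the span between the
#'   first and last overlapped target base instead of keeping the original
#'   span (off by default; see Details).
#' @details The default keeps the original segment span because the
#'   whole-exome copy-number features still use 10-40 Mb and >40 Mb size
#'   bins, which exon-clipped fragments could never reach.
#' @return The retained (possibly clipped) subset of `segments`.
#' @export
downsample_segments <- function(segments, exome, clip = FALSE) {
  stopifnot(inherits(exome, "genomic_intervals"))
  if (nrow(segments) == 0) return(segments)
  keep <- overlaps_intervals(segments$chrom, segments$start, segments$end, exome)
  out <- segments[keep, ]
  if (clip && nrow(out) > 0) {
    for (i in seq_len(nrow(out))) {
      iv <- exome[exome$chrom == out$chrom[i] &
                    exome$end > out$start[i] - 1 & exome$start < out$end[i], ]
      out$start[i] <- max(out$start[i], min(iv$start) + 1)
      out$end[i] <- min(out$end[i], max(iv$end))
    }
    out$size <- out$end - out$start + 1
  }
  out
}

#' Down-sample a whole catalogue
#'
#' Applies [downsample_mutations()] and [downsample_segments()] to the
#' mutation and segment tables of a cohort list (as produced by
#' [simulate_cohort()]), tagging the result as WES.
#'
#' @param cohort List with elements `mutations` and `segments`.
#' @param exome A [genomic_intervals()] set.
#' @param clip Passed to [downsample_segments()].
#' @return The cohort list with down-sampled tables and `assay = "WES"`.
#' @export
downsample_cohort <- function(cohort, exome, clip = FALSE) {
  cohort$mutations <- downsample_mutations(cohort$mutations, exome)
  cohort$segments <- downsample_segments(cohort$segments, exome, clip = clip)
  cohort$assay <- "WES"
  cohort
}
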