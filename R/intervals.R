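#' Genomic interval sets
#'
#' A `genomic_intervals` object is a tibble with columns `chrom`, `start`,
#' `end` holding 0-based half-open intervals, sorted and merged per
#' chromosome at construction.  It is the package's representation of exome
#' target regions and other genomic masks.
#'
#' @param chrom Character vector of chromosome names (any `chr` prefix is
#'   stripped).
#' @param start,end Integer vectors; 0-based half-open, `start < end`.
#' @return A `genomic_intervals` tibble (merged, sorted).
#' @export
#' @examples
#' genomic_intervals(c("1", "1"), c(0, 5), c(10, 20))
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  keep <- start < end
  if (any(!keep)) {
    warning(sum(!keep), " interval(s) with start >= end dropped")
  }
  df <- tibble::tibble(
    chrom = strip_chr(as.character(chrom[keep])),
    start = as.numeric(start[keep]),
    end   = as.numeric(end[keep])
  )
  merged <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
      tibble::tibble(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start)
  structure(merged, class = c("genomic_intervals", class(merged)))
}

#' @export
print.genomic_intervals <- function(x, ...) {
  cat("<genomic_intervals> ", nrow(x), " interval(s), ",
      format(covered_length(x), big.mark = ","), " bp covered\n", sep = "")
  NextMethod()
}

#' Total number of bases covered by an interval set
#'
#' @param intervals A [genomic_intervals()] object.
#' @return Numeric scalar, total covered length in bases.
#' @export
covered_length <- function(intervals) {
  sum(intervals$end - intervals$start)
}

# Vectorized overlap of 1-based closed query spans against an interval set.
# Returns a logical: does [start, end] (1-based inclusive) overlap any
# interval on the same chromosome?
overlaps_intervals <- function(chrom, start, end, intervals) {
  chrom <- strip_chr(as.character(chrom))
  hit <- logical(length(chrom))
  if (nrow(intervals) == 0 || length(chrom) == 0) return(hit)
  for (cc in unique(chrom)) {
    iv <- intervals[intervals$chrom == cc, ]
    idx <- which(chrom == cc)
    if (nrow(iv) == 0) next
    q <- IRanges::IRanges(start[idx], end[idx])
    s <- IRanges::IRanges(iv$start + 1, iv$end)
    hit[idx] <- IRanges::overlapsAny(q, s)
  }
  hit
}

strip_chr <- function(x) sub("^chr", "", x, ignore.case = TRUE)
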