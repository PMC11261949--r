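# Canonical channel orders for the three mutational-context schemas.
# These constants are the specification of record for every matrix built or
# read by the package; channel strings follow the COSMIC conventions
# (pyrimidine-referenced trinucleotides, SigProfiler-style indel channels,
# allele-specific copy-number channels).

BASES <- c("A", "C", "G", "T")

#' Canonical SBS-96 channel order
#'
#' Single base substitutions are referenced to the pyrimidine strand, giving
#' six substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each observed in the
#' 16 possible trinucleotide contexts.  Channels are written `X[R>A]Y` where
#' `R` is the pyrimidine reference base and `X`/`Y` the 5' and 3' flanking
#' bases.  Order is substitution-major, then 5' flank, then 3' flank, each
#' alphabetical.
#'
#' @return Character vector of 96 channel names in canonical order.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  as.character(unlist(lapply(subs, function(s) {
    outer(BASES, BASES, function(x, y) paste0(x, "[", s, "]", y))
  })))
}

#' Canonical ID-83 channel order
#'
#' Small insertions and deletions are classified by length, by the deleted or
#' inserted base (pyrimidine-referenced, C or T) for 1 bp events together with
#' the length of the homopolymer they sit in, by the number of adjacent copies
#' of the indel motif for longer events at repeats, and, for deletions of 2 bp
#' or more that are not at repeats, by the length of flanking microhomology.
#'
#' The trailing number counts *additional* copies of the motif adjacent to a
#' deletion (0 means the deleted copy is the only one) or the pre-existing
#' copies adjacent to an insertion, capped at 5; microhomology channels carry
#' the microhomology length, capped at 5 and never exceeding one less than
#' the deletion length.
#'
#' @return Character vector of 83 channel names in canonical order.
#' @export
id83_channels <- function() {
  one_bp <- as.character(t(outer(
    c("1:Del:C", "1:Del:T", "1:Ins:C", "1:Ins:T"), 0:5, paste, sep = ":"
  )))
  rep_del <- as.character(t(outer(paste0(2:5, ":Del:R"), 0:5, paste, sep = ":")))
  rep_ins <- as.character(t(outer(paste0(2:5, ":Ins:R"), 0:5, paste, sep = ":")))
  mh <- unlist(lapply(2:5, function(len) {
    paste0(len, ":Del:M:", seq_len(ifelse(len == 5, 5, len - 1)))
  }))
  c(one_bp, rep_del, rep_ins, mh)
}

CN_SIZE_BINS <- c("0-100kb", "100kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", ">40Mb")

#' Canonical CN-48 channel order
#'
#' Allele-specific copy-number segments are classified by zygosity
#' (homozygous deletion, loss of heterozygosity, heterozygous), total copy
#' number (TCN) bin, and segment-size bin.  Homozygous deletions use three
#' size bins; LOH segments use five TCN bins (1, 2, 3-4, 5-8, 9+) and
#' heterozygous segments four (2, 3-4, 5-8, 9+), each crossed with five size
#' bins, for 3 + 25 + 20 = 48 channels.
#'
#' @return Character vector of 48 channel names in canonical order.
#' @export
cn48_channels <- function() {
  homdel <- paste0("0:homdel:", c("0-100kb", "100kb-1Mb", ">1Mb"))
  loh <- as.character(t(outer(
    paste0(c("1", "2", "3-4", "5-8", "9+"), ":LOH"), CN_SIZE_BINS, paste, sep = ":"
  )))
  het <- as.character(t(outer(
    paste0(c("2", "3-4", "5-8", "9+"), ":het"), CN_SIZE_BINS, paste, sep = ":"
  )))
  c(homdel, loh, het)
}

#' Channel order for a variant class
#'
#' @param variant_class One of `"SBS96"`, `"ID83"`, `"CN48"`.
#' @return Character vector of channel names in canonical order.
#' @export
channel_order <- function(variant_class) {
  switch(match.arg(variant_class, c("SBS96", "ID83", "CN48")),
    SBS96 = sbs96_channels(),
    ID83  = id83_channels(),
    CN48  = cn48_channels()
  )
}

# Channels aggregated into the N[C>T]G and N[C>G]T substitution features.
NCTG_CHANNELS <- paste0(BASES, "[C>T]G")
NCGT_CHANNELS <- paste0(BASES, "[C>G]T")

# Indel channels aggregated into DEL.5.MH: deletions of >= 5 bp with
# flanking microhomology of any length.
DEL5_MH_CHANNELS <- paste0("5:Del:M:", 1:5)
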