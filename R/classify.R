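# Context classification: every somatic substitution, indel, and
# allele-specific copy-number segment is assigned to one of the 96 / 83 / 48
# canonical channels that the feature engineering operates on.

#' Context matrix constructor
#'
#' A `context_matrix` is an integer channels-by-samples matrix whose rows are
#' the full canonical channel set of one variant class, in canonical order.
#'
#' @param counts Integer matrix (rows: channels, columns: samples).
#' @param variant_class One of `"SBS96"`, `"ID83"`, `"CN48"`.
#' @return A `context_matrix` object.
#' @export
context_matrix <- function(counts, variant_class) {
  chans <- channel_order(variant_class)
  stopifnot(identical(rownames(counts), chans), all(counts >= 0))
  storage.mode(counts) <- "integer"
  structure(counts, variant_class = variant_class,
            class = c("context_matrix", "matrix", "array"))
}

#' @export
print.context_matrix <- function(x, ...) {
  cat("<context_matrix> ", attr(x, "variant_class"), ": ",
      nrow(x), " channels x ", ncol(x), " sample(s); ",
      sum(x), " events\n", sep = "")
  invisible(x)
}

#' @export
#' @method as_tibble context_matrix
#' @importFrom tibble as_tibble
as_tibble.context_matrix <- function(x, ...) {
  tibble::as_tibble(unclass_matrix(x), rownames = "channel")
}

#' Classify single-base substitutions into SBS-96 channels
#'
#' Substitutions are referenced to the pyrimidine strand: when the reference
#' base is a purine, the reference, alternate, and trinucleotide context are
#' reverse-complemented before channel assignment, so a mutation and its
#' reverse-complement presentation always map to the same channel.
#'
#' @param ref,alt Single-base reference and alternate alleles.
#' @param context Reference trinucleotide centred on the mutated base.
#' @return Character vector of SBS-96 channel names; `NA` where the context
#'   centre disagrees with `ref` or contains non-ACGT bases.
#' @export
#' @examples
#' classify_sbs("C", "T", "ACG")  # "A[C>T]G"
#' classify_sbs("G", "C", "AGT")  # reverse-complemented: "A[C>G]T"
classify_sbs <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n); context <- rep_len(context, n)
  out <- rep(NA_character_, n)
  valid <- nchar(ref) == 1 & nchar(alt) == 1 & nchar(context) == 3 &
    grepl("^[ACGT]{3}$", context) & substr(context, 2, 2) == ref & ref != alt
  if (!any(valid)) return(out)
  r <- ref[valid]; a <- alt[valid]; ctx <- context[valid]
  flip <- r %in% c("A", "G")
  if (any(flip)) {
    r[flip] <- chartr("ACGT", "TGCA", r[flip])
    a[flip] <- chartr("ACGT", "TGCA", a[flip])
    ctx[flip] <- revcomp(ctx[flip])
  }
  out[valid] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  out
}

#' Microhomology length of a deletion
#'
#' The microhomology length is the longer of (i) the longest prefix of the
#' deleted sequence that also begins the 3' flank and (ii) the longest
#' suffix that also ends the 5' flank.  A full-length match means the
#' deletion sits in a repeat tract rather than at a microhomology, so this
#' operation returns 0 and the caller routes the event to a repeat channel.
#'
#' @param deleted Deleted sequence (anchor base already stripped).
#' @param flank5,flank3 Flanking reference sequence 5' and 3' of the deleted
#'   bases, each at least as long as `deleted`.
#' @return Integer vector of microhomology lengths (0 for none or for
#'   full-length repeat matches).
#' @export
#' @examples
#' microhomology_length("TAGGC", "CCCCC", "TAGTT")  # 3
microhomology_length <- function(deleted, flank5, flank3) {
  mapply(function(s, f5, f3) {
    L <- nchar(s)
    if (L < 1) return(0L)
    p <- match_len(s, f3, from_start = TRUE)
    q <- match_len(s, f5, from_start = FALSE)
    if (p == L || q == L) return(0L)
    max(p, q)
  }, toupper(deleted), toupper(flank5), toupper(flank3), USE.NAMES = FALSE)
}

# Length of the maximal contiguous match between `s` and a flank:
# from_start = TRUE compares prefixes of s with the start of the flank,
# FALSE compares suffixes of s with the end of the flank.
match_len <- function(s, flank, from_start) {
  L <- min(nchar(s), nchar(flank))
  k <- 0L
  while (k < L) {
    a <- if (from_start) substr(s, k + 1, k + 1) else
      substr(s, nchar(s) - k, nchar(s) - k)
    b <- if (from_start) substr(flank, k + 1, k + 1) else
      substr(flank, nchar(flank) - k, nchar(flank) - k)
    if (a != b) break
    k <- k + 1L
  }
  k
}

# Number of complete adjacent copies of `motif` in the flanks (prefix copies
# of the 3' flank plus suffix copies of the 5' flank).
repeat_copies <- function(motif, flank5, flank3) {
  L <- nchar(motif)
  n3 <- 0L
  while (substr(flank3, n3 * L + 1, (n3 + 1) * L) == motif) n3 <- n3 + 1L
  n5 <- 0L
  while (n5 * L + L <= nchar(flank5) &&
         substr(flank5, nchar(flank5) - (n5 + 1) * L + 1,
                nchar(flank5) - n5 * L) == motif) n5 <- n5 + 1L
  n3 + n5
}

# Homopolymer run of `base` adjacent to a 1 bp indel site.
homopolymer_run <- function(base, flank5, flank3) {
  run3 <- match_len(strrep(base, nchar(flank3)), flank3, TRUE)
  run5 <- match_len(strrep(base, nchar(flank5)), flank5, FALSE)
  run3 + run5
}

#' Classify small insertions and deletions into ID-83 channels
#'
#' Alleles follow the VCF anchor convention; the shared anchor base is
#' stripped before classification.  1 bp events are classified by the
#' pyrimidine-referenced base (deletion/insertion of A or G is recorded as T
#' or C) and the homopolymer context; longer events by length bin
#' (2, 3, 4, 5+) and the number of adjacent copies of the motif; deletions
#' with no adjacent copy but flanking microhomology go to the
#' microhomology channels.
#'
#' @param ref,alt Anchored VCF alleles (one must be a prefix of the other).
#' @param flank5 Reference sequence ending at the anchor base (inclusive).
#' @param flank3 Reference sequence beginning immediately after the
#'   reference allele.
#' @return Character vector of ID-83 channel names; `NA` for unclassifiable
#'   records (non-ACGT alleles, non-anchored events).
#' @export
#' @examples
#' # deletion of TAGGC with 3 bp of microhomology in the 3' flank
#' classify_indel("ATAGGC", "A", "GGTCA", "TAGTT")  # "5:Del:M:3"
classify_indel <- function(ref, alt, flank5, flank3) {
  mapply(classify_indel_one, toupper(ref), toupper(alt),
         toupper(flank5), toupper(flank3), USE.NAMES = FALSE)
}

classify_indel_one <- function(ref, alt, flank5, flank3) {
  cls <- classify_variant(ref, alt)
  if (!cls %in% c("DEL", "INS")) return(NA_character_)
  s <- if (cls == "DEL") substr(ref, nchar(alt) + 1, nchar(ref)) else
    substr(alt, nchar(ref) + 1, nchar(alt))
  if (!grepl("^[ACGT]+$", s)) return(NA_character_)
  L <- nchar(s)
  type <- if (cls == "DEL") "Del" else "Ins"
  if (L == 1) {
    run <- homopolymer_run(s, flank5, flank3)
    base <- if (s %in% c("A", "G")) chartr("AG", "TC", s) else s
    return(paste0("1:", type, ":", base, ":", min(run, 5L)))
  }
  len_bin <- min(L, 5L)
  r <- repeat_copies(s, flank5, flank3)
  if (cls == "DEL" && r == 0) {
    m <- microhomology_length(s, flank5, flank3)
    if (m >= 1) {
      return(paste0(len_bin, ":Del:M:", min(m, ifelse(len_bin == 5, 5L, len_bin - 1L))))
    }
  }
  paste0(len_bin, ":", type, ":R:", min(r, 5L))
}

#' Classify allele-specific copy-number segments into CN-48 channels
#'
#' Channel assignment uses (i) zygosity: homozygous deletion (TCN = 0), LOH
#' (minor copy number 0, TCN >= 1), or heterozygous (minor >= 1); (ii) the
#' total-copy-number bin; and (iii) the segment-size bin.  Size bins are
#' half-open on the upper side (e.g. "1Mb-10Mb" means more than 1 Mb and at
#' most 10 Mb).
#'
#' @param major_cn,minor_cn Non-negative integer allele-specific copy
#'   numbers (major >= minor).
#' @param size Segment length in bases (`end - start + 1`).
#' @return Character vector of CN-48 channel names.
#' @export
#' @examples
#' classify_cn(1, 0, 25e6)  # "1:LOH:10Mb-40Mb"
classify_cn <- function(major_cn, minor_cn, size) {
  tcn <- major_cn + minor_cn
  stopifnot(all(major_cn >= minor_cn), all(minor_cn >= 0), all(size >= 1))
  size_bin <- dplyr::case_when(
    size <= 1e5 ~ "0-100kb",
    size <= 1e6 ~ "100kb-1Mb",
    size <= 1e7 ~ "1Mb-10Mb",
    size <= 4e7 ~ "10Mb-40Mb",
    TRUE ~ ">40Mb"
  )
  homdel_bin <- dplyr::case_when(
    size <= 1e5 ~ "0-100kb",
    size <= 1e6 ~ "100kb-1Mb",
    TRUE ~ ">1Mb"
  )
  tcn_bin <- dplyr::case_when(
    tcn <= 2 ~ as.character(tcn),
    tcn <= 4 ~ "3-4",
    tcn <= 8 ~ "5-8",
    TRUE ~ "9+"
  )
  dplyr::case_when(
    tcn == 0 ~ paste0("0:homdel:", homdel_bin),
    minor_cn == 0 ~ paste0(tcn_bin, ":LOH:", size_bin),
    TRUE ~ paste0(tcn_bin, ":het:", size_bin)
  )
}

# Classify a table of mutations against a reference genome, returning the
# per-record channel (NA = unclassifiable) for the requested class.
classify_mutations <- function(mutations, genome, variant_class) {
  out <- rep(NA_character_, nrow(mutations))
  if (variant_class == "SBS96") {
    idx <- which(mutations$variant_class == "SBS")
    if (length(idx)) {
      ctx <- get_trinucleotide(genome, mutations$chrom[idx], mutations$pos[idx])
      out[idx] <- classify_sbs(mutations$ref[idx], mutations$alt[idx], ctx)
    }
  } else if (variant_class == "ID83") {
    idx <- which(mutations$variant_class %in% c("DEL", "INS"))
    chroms <- strip_chr(mutations$chrom[idx])
    for (cc in unique(chroms)) {
      if (!cc %in% names(genome)) {
        stop("chromosome '", cc, "' not present in the reference")
      }
      s <- as.character(genome[[cc]])
      ii <- idx[chroms == cc]
      pos <- mutations$pos[ii]
      ref <- mutations$ref[ii]; alt <- mutations$alt[ii]
      flank_len <- pmax(6L * abs(nchar(ref) - nchar(alt)), 10L)
      ref_end <- pos + nchar(ref) - 1
      flank5 <- substring(s, pmax(1, pos - flank_len + 1), pos)
      flank3 <- substring(s, ref_end + 1,
                          pmin(nchar(s), ref_end + flank_len))
      ref_obs <- substring(s, pos, pmin(nchar(s), ref_end))
      chan <- classify_indel(ref, alt, flank5, flank3)
      chan[ref_obs != ref] <- NA_character_  # reference mismatch: excluded
      out[ii] <- chan
    }
  } else {
    stop("variant_class must be SBS96 or ID83 for mutation tables")
  }
  out
}

#' Build a channel-by-sample context matrix
#'
#' Counts every classifiable event of one variant class.  For `"SBS96"` and
#' `"ID83"` a mutation table and reference genome are required; for
#' `"CN48"` a segment table.  Events that cannot be classified (reference
#' mismatch, non-ACGT alleles, `OTHER` variant class) are excluded and
#' reported in the `exclusions` attribute; per-sample column sums therefore
#' equal the number of classifiable events.
#'
#' @param records Mutation table ([mutation_records()]) or segment table
#'   ([segment_records()]).
#' @param variant_class One of `"SBS96"`, `"ID83"`, `"CN48"`.
#' @param genome Reference `DNAStringSet` (required for mutation classes).
#' @param samples Optional character vector fixing the column set/order;
#'   defaults to the samples present in `records`.  Samples with zero
#'   classifiable events keep an all-zero column with a warning.
#' @return A [context_matrix()] with an `exclusions` attribute (tibble of
#'   excluded records and reasons).
#' @export
build_context_matrix <- function(records, variant_class, genome = NULL,
                                 samples = NULL) {
  variant_class <- match.arg(variant_class, c("SBS96", "ID83", "CN48"))
  if (variant_class == "CN48") {
    channel <- classify_cn(records$major_cn, records$minor_cn, records$size)
  } else {
    stopifnot(!is.null(genome))
    channel <- classify_mutations(records, genome, variant_class)
  }
  if (is.null(samples)) samples <- unique(records$sample_id)
  chans <- channel_order(variant_class)
  counts <- matrix(0L, length(chans), length(samples),
                   dimnames = list(chans, samples))
  keep <- !is.na(channel) & records$sample_id %in% samples
  if (any(keep)) {
    tab <- table(factor(channel[keep], levels = chans),
                 factor(records$sample_id[keep], levels = samples))
    counts <- counts + as.integer(tab)
    dim(counts) <- c(length(chans), length(samples))
    dimnames(counts) <- list(chans, samples)
  }
  zero <- samples[colSums(counts) == 0]
  excl_idx <- if (variant_class == "CN48") {
    which(is.na(channel))
  } else {
    relevant <- if (variant_class == "SBS96") "SBS" else c("DEL", "INS")
    which(is.na(channel) & records$variant_class %in% relevant)
  }
  exclusions <- if (length(excl_idx)) {
    dplyr::mutate(records[excl_idx, ], reason = "unclassifiable")
  } else {
    dplyr::mutate(records[0, ], reason = character())
  }
  if (length(zero)) {
    warning("sample(s) with zero classifiable ", variant_class, " events: ",
            paste(utils::head(zero, 5), collapse = ", "))
  }
  out <- context_matrix(counts, variant_class)
  attr(out, "exclusions") <- exclusions
  out
}
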