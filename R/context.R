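# Reference-sequence access.  The toy/real genome is held as a
# Biostrings::DNAStringSet; chromosome names are normalised (first word of
# the FASTA header, "chr" prefix stripped) so that mutation tables from
# mixed sources match.

#' Load a reference genome from FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A `DNAStringSet` with normalised chromosome names.
#' @export
load_reference <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- strip_chr(sub("\\s.*$", "", names(genome)))
  genome
}

# Extract [start, end] (1-based, clamped to the chromosome) as an upper-case
# character string.  Vectorized over positions within one call via loop;
# callers batch per chromosome.
get_sequence <- function(genome, chrom, start, end) {
  chrom <- strip_chr(as.character(chrom))
  n <- length(chrom)
  out <- character(n)
  for (cc in unique(chrom)) {
    if (!cc %in% names(genome)) {
      stop("chromosome '", cc, "' not present in the reference")
    }
    idx <- which(chrom == cc)
    len <- length(genome[[cc]])
    s <- pmax(1, pmin(start[idx], len + 1))
    e <- pmin(len, pmax(end[idx], 0))
    views <- Biostrings::Views(genome[[cc]], start = pmin(s, e + 1), end = e)
    out[idx] <- as.character(views)
  }
  toupper(out)
}

# The reference 3-mer centred on a position.
get_trinucleotide <- function(genome, chrom, pos) {
  get_sequence(genome, chrom, pos - 1, pos + 1)
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, "", fixed = TRUE),
                                function(ch) paste(rev(ch), collapse = ""),
                                character(1)))
}
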