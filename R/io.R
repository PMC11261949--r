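# Readers and writers for the tabular formats the pipeline touches:
# minimal VCF and TSV mutation tables, ASCAT-style segment tables, BED3
# interval files, and channel-by-sample context matrices.  All downstream
# code consumes the tibbles produced here; coordinate conventions are fixed
# at this boundary (mutations and segments 1-based, BED 0-based half-open)
# and any "chr" prefix is stripped from chromosome names.

#' Build a mutation record table
#'
#' Validates raw substitution/indel calls and assigns each record a variant
#' class: `SBS` for single-base substitutions, `DEL`/`INS` for
#' anchor-convention deletions and insertions (the alternate allele is a
#' prefix of the reference, or vice versa), and `OTHER` for anything else
#' (multi-nucleotide substitutions and complex indels), which downstream
#' classification excludes.
#'
#' @param sample_id,chrom Character vectors.
#' @param pos Integer vector, 1-based position of the first reference base.
#' @param ref,alt DNA strings (`[ACGT]+`), upper-cased on ingestion.
#' @return Tibble with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class`.
#' @export
mutation_records <- function(sample_id, chrom, pos, ref, alt) {
  df <- tibble::tibble(
    sample_id = as.character(sample_id),
    chrom = strip_chr(as.character(chrom)),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt))
  )
  ok <- grepl("^[ACGT]+$", df$ref) & grepl("^[ACGT]+$", df$alt) &
    df$ref != df$alt & !is.na(df$pos) & df$pos >= 1
  if (any(!ok)) {
    stop("invalid mutation record(s) at row(s): ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  df$variant_class <- classify_variant(df$ref, df$alt)
  df
}

classify_variant <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("OTHER", max(length(ref), length(alt)))
  out[nr == 1 & na == 1] <- "SBS"
  out[nr > na & startsWith(ref, alt)] <- "DEL"
  out[na > nr & startsWith(alt, ref)] <- "INS"
  out
}

#' Read somatic mutations from a minimal VCF or a tabular TSV
#'
#' The `vcf_minimal` dialect honours columns 1-5 (CHROM, POS, ID, REF, ALT)
#' of a single-sample VCF and ignores the rest; multi-allelic ALT fields are
#' split into one record per alternate allele.  The `tabular` dialect reads a
#' header-bearing TSV with columns `sample`, `chrom`, `pos`, `ref`, `alt`.
#' Malformed rows are never silently dropped: they are collected into a
#' parse report (a tibble of line numbers and reasons) attached as the
#' `parse_report` attribute and retrievable with [parse_report()].
#'
#' @param path Path to the file.
#' @param dialect `"vcf_minimal"` or `"tabular"`; `"auto"` treats files whose
#'   first non-empty line starts with `##` or `#CHROM` as VCF.
#' @param sample_id Sample name to assign for VCF input (defaults to the
#'   file name without extension).
#' @return Tibble of mutation records (see [mutation_records()]) with a
#'   `parse_report` attribute.
#' @export
read_mutations <- function(path, dialect = c("auto", "vcf_minimal", "tabular"),
                           sample_id = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (dialect == "auto") {
    first <- lines[nzchar(lines)][1]
    dialect <- if (!is.na(first) && startsWith(first, "#")) "vcf_minimal" else "tabular"
  }
  if (dialect == "vcf_minimal") {
    read_mutations_vcf(lines, path, sample_id)
  } else {
    read_mutations_tabular(lines, path)
  }
}

read_mutations_vcf <- function(lines, path, sample_id) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf$", "", basename(path), ignore.case = TRUE)
  }
  data_idx <- which(nzchar(lines) & !startsWith(lines, "#"))
  rows <- list(); report <- list()
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t|[ ]+")[[1]]
    if (length(f) < 5 || is.na(suppressWarnings(as.integer(f[2])))) {
      report[[length(report) + 1]] <- tibble::tibble(line = i, reason = "malformed VCF row")
      next
    }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    for (a in alts) {
      if (!grepl("^[ACGTacgt]+$", a) || !grepl("^[ACGTacgt]+$", f[4]) ||
          toupper(a) == toupper(f[4])) {
        report[[length(report) + 1]] <-
          tibble::tibble(line = i, reason = paste0("unsupported allele '", a, "'"))
        next
      }
      rows[[length(rows) + 1]] <- list(sample_id = sample_id, chrom = f[1],
                                       pos = as.integer(f[2]), ref = f[4], alt = a)
    }
  }
  finish_mutation_read(rows, report, length(data_idx) == 0)
}

read_mutations_tabular <- function(lines, path) {
  df <- suppressMessages(readr::read_tsv(I(lines), show_col_types = FALSE,
                                         progress = FALSE))
  names(df) <- tolower(names(df))
  need <- c("sample", "chrom", "pos", "ref", "alt")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  rows <- list(); report <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    pos <- suppressWarnings(as.integer(r$pos))
    bad <- is.na(pos) || pos < 1 ||
      !grepl("^[ACGTacgt]+$", r$ref) || !grepl("^[ACGTacgt]+$", r$alt) ||
      toupper(r$ref) == toupper(r$alt)
    if (bad) {
      report[[length(report) + 1]] <- tibble::tibble(line = i + 1L, reason = "malformed row")
      next
    }
    for (a in strsplit(as.character(r$alt), ",", fixed = TRUE)[[1]]) {
      rows[[length(rows) + 1]] <- list(sample_id = as.character(r$sample),
                                       chrom = as.character(r$chrom),
                                       pos = pos, ref = as.character(r$ref), alt = a)
    }
  }
  finish_mutation_read(rows, report, nrow(df) == 0)
}

finish_mutation_read <- function(rows, report, empty) {
  if (empty) warning("no data rows found")
  out <- if (length(rows)) {
    d <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    mutation_records(d$sample_id, d$chrom, d$pos, d$ref, d$alt)
  } else {
    mutation_records(character(), character(), integer(), character(), character())
  }
  attr(out, "parse_report") <- if (length(report)) dplyr::bind_rows(report) else
    tibble::tibble(line = integer(), reason = character())
  out
}

#' Retrieve the parse report attached by a reader
#'
#' @param x Object returned by [read_mutations()] or [read_segments()].
#' @return Tibble with columns `line` and `reason`.
#' @export
parse_report <- function(x) {
  rep <- attr(x, "parse_report")
  if (is.null(rep)) tibble::tibble(line = integer(), reason = character()) else rep
}

#' Build an allele-specific copy-number segment table
#'
#' @param sample_id,chrom Character vectors.
#' @param start,end 1-based inclusive segment bounds, `end >= start`.
#' @param major_cn,minor_cn Non-negative integer allele-specific copy
#'   numbers; rows with `major_cn < minor_cn` are swapped with a warning.
#' @return Tibble with the input columns plus derived `tcn` (total copy
#'   number) and `size` (`end - start + 1`, bases).
#' @export
segment_records <- function(sample_id, chrom, start, end, major_cn, minor_cn) {
  df <- tibble::tibble(
    sample_id = as.character(sample_id),
    chrom = strip_chr(as.character(chrom)),
    start = as.numeric(start), end = as.numeric(end),
    major_cn = as.integer(major_cn), minor_cn = as.integer(minor_cn)
  )
  stopifnot(all(df$end >= df$start), all(df$major_cn >= 0), all(df$minor_cn >= 0))
  swap <- df$major_cn < df$minor_cn
  if (any(swap)) {
    warning(sum(swap), " segment(s) had major_cn < minor_cn; swapped")
    tmp <- df$major_cn[swap]
    df$major_cn[swap] <- df$minor_cn[swap]
    df$minor_cn[swap] <- tmp
  }
  df$tcn <- df$major_cn + df$minor_cn
  df$size <- df$end - df$start + 1
  df
}

#' Read ASCAT-style allele-specific copy-number segments
#'
#' Expects a TSV with columns `sample`, `chrom`, `start`, `end`,
#' `major_cn`/`nMajor` and `minor_cn`/`nMinor` (header synonyms resolved
#' case-insensitively).  Rows with negative or non-integer copy numbers are
#' rejected into the parse report; subclonal (fractional) copy numbers are
#' not supported.
#'
#' @param path Path to the TSV.
#' @return Tibble of segment records (see [segment_records()]) with a
#'   `parse_report` attribute.
#' @export
read_segments <- function(path) {
  stopifnot(file.exists(path))
  df <- suppressMessages(readr::read_tsv(path, show_col_types = FALSE,
                                         progress = FALSE))
  nm <- tolower(names(df))
  synonyms <- list(
    sample = c("sample", "sample_id"),
    chrom = c("chrom", "chr", "chromosome"),
    start = c("start", "startpos", "start_pos"),
    end = c("end", "endpos", "end_pos"),
    major_cn = c("major_cn", "nmajor", "major"),
    minor_cn = c("minor_cn", "nminor", "minor")
  )
  idx <- vapply(synonyms, function(s) {
    i <- which(nm %in% s)
    if (length(i) == 0) NA_integer_ else i[1]
  }, integer(1))
  if (any(is.na(idx))) {
    stop("missing required column(s): ",
         paste(names(synonyms)[is.na(idx)], collapse = ", "))
  }
  df <- df[, idx]
  names(df) <- names(synonyms)
  num <- suppressWarnings(cbind(as.numeric(df$major_cn), as.numeric(df$minor_cn)))
  bad <- is.na(num[, 1]) | is.na(num[, 2]) | num[, 1] < 0 | num[, 2] < 0 |
    num[, 1] != round(num[, 1]) | num[, 2] != round(num[, 2]) |
    is.na(suppressWarnings(as.numeric(df$start))) |
    is.na(suppressWarnings(as.numeric(df$end))) |
    suppressWarnings(as.numeric(df$end)) < suppressWarnings(as.numeric(df$start))
  bad[is.na(bad)] <- TRUE
  report <- tibble::tibble(line = which(bad) + 1L,
                           reason = rep("negative, fractional, or malformed values", sum(bad)))
  keep <- df[!bad, ]
  out <- segment_records(keep$sample, keep$chrom, keep$start, keep$end,
                         keep$major_cn, keep$minor_cn)
  attr(out, "parse_report") <- report
  out
}

#' Read a BED3 file into a genomic interval set
#'
#' @param path Path to a BED file (0-based half-open; columns beyond the
#'   third are ignored).  Rows with `start >= end` are dropped with a
#'   warning; overlapping intervals are merged.
#' @return A [genomic_intervals()] object.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(genomic_intervals())
  f <- strsplit(lines, "\t")
  genomic_intervals(
    chrom = vapply(f, `[`, "", 1),
    start = as.numeric(vapply(f, `[`, "", 2)),
    end = as.numeric(vapply(f, `[`, "", 3))
  )
}

#' Write / read a channel-by-sample context matrix
#'
#' The TSV has channel names in the first column (named `channel`) and one
#' integer column per sample; round-tripping is lossless.  On read, the row
#' set must be exactly the canonical channel set of `variant_class`.
#'
#' @param matrix A [context_matrix()] object.
#' @param path Output / input path.
#' @return `write_context_matrix()` returns `path` invisibly;
#'   `read_context_matrix()` returns a [context_matrix()].
#' @export
write_context_matrix <- function(matrix, path) {
  df <- tibble::as_tibble(unclass_matrix(matrix), rownames = "channel")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_context_matrix
#' @param variant_class One of `"SBS96"`, `"ID83"`, `"CN48"`.
#' @export
read_context_matrix <- function(path, variant_class) {
  chans <- channel_order(variant_class)
  df <- suppressMessages(readr::read_tsv(path, show_col_types = FALSE,
                                         progress = FALSE))
  unknown <- setdiff(df$channel, chans)
  if (length(unknown)) {
    stop("unknown channel name(s): ", paste(utils::head(unknown, 3), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$channel
  full <- matrix(0L, length(chans), ncol(m),
                 dimnames = list(chans, colnames(m)))
  full[rownames(m), ] <- as.integer(m)
  context_matrix(full, variant_class)
}

unclass_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "variant_class") <- NULL
  m
}
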