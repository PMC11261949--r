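# Independent brute-force oracles.  These deliberately re-derive every
# classification from first principles by different routes than the package
# (lookup tables, per-base scans, exhaustive prefix/suffix comparison,
# hypergeometric sums) so that agreement is informative.

# -- SBS-96: exhaustive lookup table built with Biostrings ------------------
oracle_sbs96_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    bases <- c("A", "C", "G", "T")
    grid <- expand.grid(up = bases, ref = bases, dn = bases, alt = bases,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$ref != grid$alt, ]
    rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
    chan <- character(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      if (g$ref %in% c("A", "G")) {
        ctx <- rc(paste0(g$up, g$ref, g$dn))
        ref <- rc(g$ref); alt <- rc(g$alt)
      } else {
        ctx <- paste0(g$up, g$ref, g$dn); ref <- g$ref; alt <- g$alt
      }
      chan[i] <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                        substr(ctx, 3, 3))
    }
    grid$channel <- chan
    tab <<- grid
    tab
  }
})

oracle_sbs96 <- function(ref, alt, context) {
  tab <- oracle_sbs96_table()
  key <- paste(substr(context, 1, 1), ref, substr(context, 3, 3), alt)
  tab_key <- paste(tab$up, tab$ref, tab$dn, tab$alt)
  tab$channel[match(key, tab_key)]
}

# -- microhomology: exhaustive prefix/suffix scan ---------------------------
oracle_mh <- function(deleted, flank5, flank3) {
  L <- nchar(deleted)
  best_p <- 0L
  for (k in seq_len(L)) {
    if (substr(deleted, 1, k) == substr(flank3, 1, k)) best_p <- k else break
  }
  best_s <- 0L
  for (k in seq_len(L)) {
    if (substr(deleted, L - k + 1, L) ==
        substr(flank5, nchar(flank5) - k + 1, nchar(flank5))) {
      best_s <- k
    } else break
  }
  if (best_p == L || best_s == L) return(0L)
  max(best_p, best_s)
}

# -- ID-83: independent re-derivation with string scans ---------------------
oracle_id83 <- function(ref, alt, flank5, flank3) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) return(NA_character_)
  is_del <- nr > na
  if (is_del && substr(ref, 1, na) != alt) return(NA_character_)
  if (!is_del && substr(alt, 1, nr) != ref) return(NA_character_)
  s <- if (is_del) substring(ref, na + 1) else substring(alt, nr + 1)
  if (grepl("[^ACGT]", s)) return(NA_character_)
  L <- nchar(s)
  type <- if (is_del) "Del" else "Ins"
  # adjacent copies of the motif: scan outward in both directions
  copies <- 0L
  off <- 1L
  while (substr(flank3, off, off + L - 1) == s && off + L - 1 <= nchar(flank3)) {
    copies <- copies + 1L; off <- off + L
  }
  off <- nchar(flank5)
  while (off - L + 1 >= 1 && substr(flank5, off - L + 1, off) == s) {
    copies <- copies + 1L; off <- off - L
  }
  if (L == 1) {
    base <- c(A = "T", C = "C", G = "C", T = "T")[[s]]
    return(paste0("1:", type, ":", base, ":", min(copies, 5L)))
  }
  lb <- min(L, 5L)
  if (is_del && copies == 0L) {
    m <- oracle_mh(s, flank5, flank3)
    if (m >= 1) return(paste0(lb, ":Del:M:", min(m, if (lb == 5) 5L else lb - 1L)))
  }
  paste0(lb, ":", type, ":R:", min(copies, 5L))
}

# -- CN-48: literal bounds table -------------------------------------------
oracle_cn48_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    rows <- list()
    add <- function(chan, min_tcn, max_tcn, zyg, min_size, max_size) {
      rows[[length(rows) + 1]] <<- data.frame(
        channel = chan, min_tcn = min_tcn, max_tcn = max_tcn, zyg = zyg,
        min_size = min_size, max_size = max_size, stringsAsFactors = FALSE)
    }
    hd_sizes <- list(c(0, 1e5), c(1e5, 1e6), c(1e6, Inf))
    hd_names <- c("0-100kb", "100kb-1Mb", ">1Mb")
    for (i in 1:3) add(paste0("0:homdel:", hd_names[i]), 0, 0, "homdel",
                       hd_sizes[[i]][1], hd_sizes[[i]][2])
    sizes <- list(c(0, 1e5), c(1e5, 1e6), c(1e6, 1e7), c(1e7, 4e7), c(4e7, Inf))
    size_names <- c("0-100kb", "100kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", ">40Mb")
    tcns_loh <- list(c(1, 1), c(2, 2), c(3, 4), c(5, 8), c(9, Inf))
    tcn_names_loh <- c("1", "2", "3-4", "5-8", "9+")
    for (i in seq_along(tcns_loh)) for (j in seq_along(sizes)) {
      add(paste0(tcn_names_loh[i], ":LOH:", size_names[j]),
          tcns_loh[[i]][1], tcns_loh[[i]][2], "LOH",
          sizes[[j]][1], sizes[[j]][2])
    }
    tcns_het <- list(c(2, 2), c(3, 4), c(5, 8), c(9, Inf))
    tcn_names_het <- c("2", "3-4", "5-8", "9+")
    for (i in seq_along(tcns_het)) for (j in seq_along(sizes)) {
      add(paste0(tcn_names_het[i], ":het:", size_names[j]),
          tcns_het[[i]][1], tcns_het[[i]][2], "het",
          sizes[[j]][1], sizes[[j]][2])
    }
    tab <<- do.call(rbind, rows)
    tab
  }
})

oracle_cn48 <- function(major, minor, size) {
  tab <- oracle_cn48_table()
  vapply(seq_along(major), function(i) {
    tcn <- major[i] + minor[i]
    zyg <- if (tcn == 0) "homdel" else if (minor[i] == 0) "LOH" else "het"
    hit <- tab$zyg == zyg & tcn >= tab$min_tcn & tcn <= tab$max_tcn &
      size[i] > tab$min_size & size[i] <= tab$max_size
    if (sum(hit) != 1) return(NA_character_)
    tab$channel[hit]
  }, character(1))
}

# -- per-base interval overlap ---------------------------------------------
# covered: set of 0-based positions covered by the interval tibble
oracle_covered_positions <- function(intervals, chrom) {
  iv <- intervals[intervals$chrom == chrom, ]
  if (nrow(iv) == 0) return(integer())
  unlist(lapply(seq_len(nrow(iv)), function(i) seq(iv$start[i], iv$end[i] - 1)))
}

oracle_overlaps <- function(chrom, start, end, intervals) {
  vapply(seq_along(chrom), function(i) {
    cov <- oracle_covered_positions(intervals, sub("^chr", "", chrom[i]))
    any(seq(start[i], end[i]) %in% (cov + 1))
  }, logical(1))
}

# -- Fisher two-sided p: hypergeometric tail sum ----------------------------
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# -- AUC: all-pairs concordance --------------------------------------------
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
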