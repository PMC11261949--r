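# Seeded synthetic cohorts.  The generator emulates the channel contrasts
# the classifier is built on: HRD samples are enriched for N[C>G]T
# substitutions, >=5 bp deletions at microhomologies, LOH segments of
# 1-40 Mb, and heterozygous TCN 3-9 segments of 10-40 Mb, while HRP samples
# are enriched for N[C>T]G CpG transitions and very large (>40 Mb)
# heterozygous TCN 2-4 segments.  Every simulated mutation is placed on (or
# constructed against) the toy reference so that re-classification
# reproduces the intended channel exactly; copy-number segments are drawn on
# the full nominal chromosome spans, which carry no sequence because
# segment classification depends only on coordinates and copy numbers.

#' Simulation configuration
#'
#' Defaults encode the study conditions the package is exercised under:
#' 50 samples per arm, mean burdens of 600 substitutions, 150 indels and 80
#' copy-number segments per sample, and channel mixtures whose HRD/HRP
#' contrasts (3-6x on the planted channels) clear the whole-genome volcano
#' thresholds.  See the package vignette for the rationale behind each
#' default.
#'
#' @param seed Master seed; per-sample substreams are derived from it.
#' @param n_hrd,n_hrp Samples per arm.
#' @param sbs_burden,indel_burden,n_segments Poisson means per sample.
#' @param ncgt_mass,nctg_mass Named numeric `c(HRD = , HRP = )`: total
#'   probability mass on the four `N[C>G]T` / `N[C>T]G` channels.
#' @param del5_mass Named numeric: total mass on the `5:Del:M:1-5` channels.
#' @param segment_mixture Named list `HRD`/`HRP` of probabilities over the
#'   four segment types `loh_1_40mb`, `het_3_9_10_40mb`, `het_2_4_gt40mb`,
#'   `other`.
#' @param chroms Character vector of toy chromosome names.
#' @param chrom_length Nominal chromosome length in bases (the coordinate
#'   span for copy-number segments and the exome).
#' @param seq_length Sequence-realized window per chromosome (where
#'   mutations are placed).
#' @param exome_fraction Fraction of the genome covered by exome targets.
#' @param exome_interval Size of each exome target interval (bases).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_hrd = 50, n_hrp = 50,
                              sbs_burden = 600, indel_burden = 150,
                              n_segments = 80,
                              ncgt_mass = c(HRD = 0.25, HRP = 0.05),
                              nctg_mass = c(HRD = 0.05, HRP = 0.25),
                              del5_mass = c(HRD = 0.30, HRP = 0.03),
                              segment_mixture = list(
                                HRD = c(loh_1_40mb = 0.35, het_3_9_10_40mb = 0.20,
                                        het_2_4_gt40mb = 0.05, other = 0.40),
                                HRP = c(loh_1_40mb = 0.08, het_3_9_10_40mb = 0.04,
                                        het_2_4_gt40mb = 0.45, other = 0.43)
                              ),
                              chroms = c("1", "2", "3"),
                              chrom_length = 120e6,
                              seq_length = 4e5,
                              exome_fraction = 0.1,
                              exome_interval = 1000) {
  stopifnot(sbs_burden > 0, indel_burden > 0, n_segments > 0,
            seq_length >= 1e4, chrom_length >= seq_length,
            exome_fraction > 0, exome_fraction <= 1)
  for (g in c("HRD", "HRP")) {
    stopifnot(abs(sum(segment_mixture[[g]]) - 1) < 1e-9,
              ncgt_mass[[g]] + nctg_mass[[g]] < 1, del5_mass[[g]] < 1)
  }
  structure(list(
    seed = seed, n_hrd = n_hrd, n_hrp = n_hrp,
    sbs_burden = sbs_burden, indel_burden = indel_burden,
    n_segments = n_segments,
    sbs_channel_probs = list(HRD = sbs_probs(ncgt_mass[["HRD"]], nctg_mass[["HRD"]]),
                             HRP = sbs_probs(ncgt_mass[["HRP"]], nctg_mass[["HRP"]])),
    id_channel_probs = list(HRD = id_probs(del5_mass[["HRD"]]),
                            HRP = id_probs(del5_mass[["HRP"]])),
    segment_mixture = segment_mixture,
    chroms = chroms, chrom_length = chrom_length, seq_length = seq_length,
    exome_fraction = exome_fraction, exome_interval = exome_interval
  ), class = "sim_config")
}

# SBS-96 probability vector: planted mass on the N[C>G]T and N[C>T]G
# channels, remainder uniform over the other 88 channels.
sbs_probs <- function(ncgt, nctg) {
  chans <- sbs96_channels()
  p <- stats::setNames(rep((1 - ncgt - nctg) / (96 - 8), 96), chans)
  p[NCGT_CHANNELS] <- ncgt / 4
  p[NCTG_CHANNELS] <- nctg / 4
  p
}

# ID-83 probability vector: planted mass on the 5:Del:M:1-5 channels,
# remainder uniform over five common background indel channels.
ID_BACKGROUND <- c("1:Del:C:0", "1:Del:T:0", "1:Ins:C:0", "1:Ins:T:0",
                   "2:Del:R:0")
id_probs <- function(del5) {
  p <- stats::setNames(
    c(rep(del5 / 5, 5), rep((1 - del5) / length(ID_BACKGROUND),
                            length(ID_BACKGROUND))),
    c(DEL5_MH_CHANNELS, ID_BACKGROUND)
  )
  p
}

#' Build the toy reference: genome window and dispersed exome targets
#'
#' Realizes `seq_length` bases of uniform-random DNA per chromosome (the
#' window mutations are placed in) and lays exome target intervals of
#' `exome_interval` bases on a regular grid across the full nominal
#' chromosome span, covering `exome_fraction` of the genome.  Identical
#' configuration yields byte-identical FASTA/BED output.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, `reference.fa` and
#'   `exome.bed` are written there.
#' @return A `toy_reference` list: `genome` (DNAStringSet of the realized
#'   windows), `chrom_lengths` (nominal), `exome`
#'   ([genomic_intervals()]), `config`, plus internal locus caches.
#' @export
make_reference <- function(config, dir = NULL) {
  seqs <- with_seed(config$seed, {
    vapply(config$chroms, function(cc) {
      paste(sample(BASES, config$seq_length, replace = TRUE), collapse = "")
    }, character(1))
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- config$chroms

  spacing <- round(config$exome_interval / config$exome_fraction)
  starts0 <- seq(0, config$chrom_length - config$exome_interval, by = spacing)
  exome <- genomic_intervals(
    chrom = rep(config$chroms, each = length(starts0)),
    start = rep(starts0, times = length(config$chroms)),
    end = rep(starts0 + config$exome_interval, times = length(config$chroms))
  )
  ref <- list(
    genome = genome,
    chrom_lengths = stats::setNames(rep(config$chrom_length,
                                        length(config$chroms)), config$chroms),
    exome = exome,
    config = config,
    chars = lapply(stats::setNames(seqs, config$chroms), function(s) {
      strsplit(s, "", fixed = TRUE)[[1]]
    }),
    cache = new.env(parent = emptyenv())
  )
  class(ref) <- "toy_reference"
  if (!is.null(dir)) write_reference(ref, dir)
  ref
}

#' Write the toy reference FASTA and exome BED
#'
#' @param reference A `toy_reference`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  bed <- file.path(dir, "exome.bed")
  Biostrings::writeXStringSet(reference$genome, fa)
  readr::write_tsv(as.data.frame(reference$exome)[, c("chrom", "start", "end")],
                   bed, col_names = FALSE, progress = FALSE)
  invisible(c(fasta = fa, bed = bed))
}

# ---- locus machinery -------------------------------------------------------

# Pyrimidine-context trinucleotide index: pyr 3-mer -> tibble(chrom, pos),
# built once per reference and cached.
trimer_index <- function(reference) {
  if (!is.null(reference$cache$trimers)) return(reference$cache$trimers)
  tabs <- lapply(names(reference$chars), function(cc) {
    ch <- reference$chars[[cc]]
    n <- length(ch)
    p <- 2:(n - 1)
    up <- ch[p - 1]; cen <- ch[p]; dn <- ch[p + 1]
    flip <- cen %in% c("A", "G")
    comp <- function(x) chartr("ACGT", "TGCA", x)
    tri <- ifelse(flip,
                  paste0(comp(dn), comp(cen), comp(up)),
                  paste0(up, cen, dn))
    tibble::tibble(chrom = cc, pos = p, tri = tri)
  })
  all_tri <- dplyr::bind_rows(tabs)
  idx <- split(all_tri[c("chrom", "pos")], all_tri$tri)
  reference$cache$trimers <- idx
  idx
}

# Parse an ID-83 channel string into its components.
parse_id_channel <- function(channel) {
  f <- strsplit(channel, ":", fixed = TRUE)[[1]]
  list(len = as.integer(f[1]), type = f[2], sub = f[3], num = as.integer(f[4]))
}

# Pool of genomic deletion loci whose re-classification yields `channel`.
# Fast vectorized pre-filters propose candidates; every candidate is then
# verified with the classifier itself, so the pool is correct by
# construction.
del_locus_pool <- function(reference, channel) {
  key <- paste0("pool_", channel)
  if (!is.null(reference$cache[[key]])) return(reference$cache[[key]])
  info <- parse_id_channel(channel)
  pool <- dplyr::bind_rows(lapply(names(reference$chars), function(cc) {
    ch <- reference$chars[[cc]]
    n <- length(ch)
    if (info$sub %in% c("C", "T")) {
      # 1 bp deletion in a homopolymer with `num` additional copies
      r <- rle(ch)
      runlen <- rep(r$lengths, r$lengths)
      ok <- ch %in% c(info$sub, chartr("CT", "GA", info$sub)) &
        (if (info$num >= 5) runlen >= 6 else runlen == info$num + 1)
      p <- which(ok)
      p <- p[p >= 2 & p <= n - 12]
      L <- 1L
    } else if (info$sub == "M") {
      # deletion start p, deleted sequence S = ch[p .. p+L-1], 3' flank
      # begins at p+L; require S[1..k] == flank3[1..k], a mismatch at k+1,
      # and no 5'-side microhomology (ch[p-1] != S[L]).
      L <- if (info$len < 5) info$len else if (info$num == 5) 6L else 5L
      k <- info$num
      p <- seq.int(2L, n - 2L * L - k - 2L)
      keep <- rep(TRUE, length(p))
      for (j in seq_len(k)) keep <- keep & ch[p + j - 1] == ch[p + L + j - 1]
      keep <- keep & ch[p + k] != ch[p + L + k] &
        ch[p - 1] != ch[p + L - 1]
      p <- p[keep]
    } else {
      # repeat-class deletion; rejection over random positions
      L <- info$len
      p <- seq.int(2L, n - 8L * L - 2L)
    }
    if (!length(p)) return(NULL)
    if (length(p) > 4000) p <- p[round(seq(1, length(p), length.out = 4000))]
    anchor <- p - 1L
    ref_allele <- vapply(p, function(q) paste(ch[(q - 1):(q + L - 1)], collapse = ""),
                         character(1))
    alt_allele <- ch[anchor]
    flank_len <- max(6L * L, 10L)
    f5 <- vapply(p, function(q) paste(ch[max(1, q - flank_len):(q - 1)], collapse = ""),
                 character(1))
    f3 <- vapply(p, function(q) paste(ch[(q + L):min(n, q + L + flank_len - 1)],
                                      collapse = ""), character(1))
    got <- classify_indel(ref_allele, alt_allele, f5, f3)
    keep <- !is.na(got) & got == channel
    tibble::tibble(chrom = cc, pos = anchor[keep],
                   ref = ref_allele[keep], alt = alt_allele[keep])
  }))
  if (nrow(pool) == 0) {
    stop("no loci for channel ", channel,
         " in the toy reference; increase seq_length")
  }
  reference$cache[[key]] <- pool
  pool
}

# Draw `n` insertion records for `channel` by constructing inserted
# sequences at random positions and verifying with the classifier.
sample_insertions <- function(reference, channel, n) {
  info <- parse_id_channel(channel)
  out <- vector("list", n)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 200L * n + 200L) {
      stop("insertion construction for ", channel,
           " exceeded the retry cap; increase seq_length")
    }
    cc <- sample(names(reference$chars), 1)
    ch <- reference$chars[[cc]]
    p <- sample.int(length(ch) - 8L * info$len - 2L, 1) + 1L
    ins <- if (info$sub %in% c("C", "T")) {
      sample(c(info$sub, chartr("CT", "GA", info$sub)), 1)
    } else {
      paste(sample(BASES, info$len, replace = TRUE), collapse = "")
    }
    ref_allele <- ch[p]
    alt_allele <- paste0(ref_allele, ins)
    flank_len <- max(6L * info$len, 10L)
    f5 <- paste(ch[max(1, p - flank_len + 1):p], collapse = "")
    f3 <- paste(ch[(p + 1):min(length(ch), p + flank_len)], collapse = "")
    chan <- classify_indel_one(ref_allele, alt_allele, f5, f3)
    if (!is.na(chan) && chan == channel) {
      got <- got + 1L
      out[[got]] <- list(chrom = cc, pos = p, ref = ref_allele, alt = alt_allele)
    }
  }
  dplyr::bind_rows(lapply(out, tibble::as_tibble))
}

# Segment-type draw tables: (major, minor) states and size windows per
# feature class.  Sizes keep a safety margin from the bin edges so that
# rounding never crosses a boundary.
SEGMENT_TYPES <- list(
  loh_1_40mb = list(states = list(c(1L, 0L)), w = 1,
                    size = c(1.05e6, 3.95e7)),
  het_3_9_10_40mb = list(states = list(c(2L, 1L), c(3L, 1L), c(3L, 2L), c(4L, 2L)),
                         w = c(0.4, 0.3, 0.2, 0.1),
                         size = c(1.05e7, 3.95e7)),
  het_2_4_gt40mb = list(states = list(c(1L, 1L), c(2L, 1L), c(2L, 2L)),
                        w = c(0.6, 0.25, 0.15),
                        size = c(4.05e7, 7.95e7)),
  other = list(states = list(c(1L, 1L)), w = 1,
               size = c(1.1e5, 9.5e6))
)

#' Simulate one sample catalogue
#'
#' Draws Poisson event burdens, samples channels from the class mixture,
#' and realises each mutation at (or as an insertion into) a toy-reference
#' locus whose re-classification reproduces the sampled channel exactly.
#' Copy-number segments are drawn from the class segment-type mixture with
#' sizes inside the named bins.
#'
#' @param class `"HRD"` or `"HRP"`.
#' @param config A [simulation_config()].
#' @param reference A `toy_reference` from [make_reference()].
#' @param sample_id Sample name.
#' @param seed Seed for this sample's private RNG stream.
#' @return List with `mutations`, `segments`, and `intended` (the
#'   generator's channel tallies for SBS96 and ID83, for oracle
#'   comparison).
#' @export
simulate_sample <- function(class, config, reference, sample_id,
                            seed = config$seed) {
  class <- match.arg(class, c("HRD", "HRP"))
  with_seed(seed, {
    n_sbs <- stats::rpois(1, config$sbs_burden)
    n_id <- stats::rpois(1, config$indel_burden)
    n_seg <- stats::rpois(1, config$n_segments)

    # substitutions
    sbs_p <- config$sbs_channel_probs[[class]]
    sbs_chan <- if (n_sbs > 0) {
      sample(names(sbs_p), n_sbs, replace = TRUE, prob = sbs_p)
    } else character()
    idx <- trimer_index(reference)
    sbs_rows <- lapply(unique(sbs_chan), function(chan) {
      k <- sum(sbs_chan == chan)
      ctx <- paste0(substr(chan, 1, 1), substr(chan, 3, 3), substr(chan, 7, 7))
      pool <- idx[[ctx]]
      if (is.null(pool)) stop("context ", ctx, " absent from toy reference")
      rows <- pool[sample.int(nrow(pool), k, replace = TRUE), ]
      ref_base <- mapply(function(cc, p) reference$chars[[cc]][p],
                         rows$chrom, rows$pos, USE.NAMES = FALSE)
      pyr_ref <- substr(chan, 3, 3); pyr_alt <- substr(chan, 5, 5)
      alt_base <- ifelse(ref_base == pyr_ref, pyr_alt,
                         chartr("ACGT", "TGCA", pyr_alt))
      tibble::tibble(chrom = rows$chrom, pos = rows$pos,
                     ref = ref_base, alt = alt_base)
    })

    # indels
    id_p <- config$id_channel_probs[[class]]
    id_chan <- if (n_id > 0) {
      sample(names(id_p), n_id, replace = TRUE, prob = id_p)
    } else character()
    id_rows <- list()
    for (chan in unique(id_chan)) {
      k <- sum(id_chan == chan)
      rows <- if (grepl(":Ins:", chan, fixed = TRUE)) {
        sample_insertions(reference, chan, k)
      } else {
        pool <- del_locus_pool(reference, chan)
        pool[sample.int(nrow(pool), k, replace = TRUE), ]
      }
      id_rows[[chan]] <- rows
    }
    id_df <- if (length(id_rows)) dplyr::bind_rows(id_rows) else NULL

    mut <- dplyr::bind_rows(
      if (length(sbs_rows)) dplyr::bind_rows(lapply(sbs_rows, tibble::as_tibble)),
      id_df
    )
    mutations <- if (!is.null(mut) && nrow(mut)) {
      mutation_records(sample_id, mut$chrom, mut$pos, mut$ref, mut$alt)
    } else {
      mutation_records(character(), character(), integer(), character(), character())
    }

    # copy-number segments
    mix <- config$segment_mixture[[class]]
    seg_type <- if (n_seg > 0) {
      sample(names(mix), n_seg, replace = TRUE, prob = mix)
    } else character()
    seg_rows <- lapply(seg_type, function(tp) {
      spec <- SEGMENT_TYPES[[tp]]
      st <- spec$states[[sample.int(length(spec$states), 1,
                                    prob = spec$w)]]
      size <- round(stats::runif(1, spec$size[1], spec$size[2]))
      cc <- sample(config$chroms, 1)
      start <- sample.int(config$chrom_length - size, 1)
      list(chrom = cc, start = start, end = start + size - 1,
           major_cn = st[1], minor_cn = st[2])
    })
    segments <- if (length(seg_rows)) {
      d <- dplyr::bind_rows(lapply(seg_rows, tibble::as_tibble))
      segment_records(sample_id, d$chrom, d$start, d$end, d$major_cn, d$minor_cn)
    } else {
      segment_records(character(), character(), numeric(), numeric(),
                      integer(), integer())
    }

    list(
      mutations = mutations,
      segments = segments,
      intended = list(
        SBS96 = table(factor(sbs_chan, levels = sbs96_channels())),
        ID83 = table(factor(id_chan, levels = id83_channels())),
        segment_types = table(factor(seg_type, levels = names(SEGMENT_TYPES)))
      )
    )
  })
}

#' Simulate a labelled HRD/HRP cohort
#'
#' Generates `n_hrd + n_hrp` samples with independent per-sample RNG
#' streams derived from the master seed, so the cohort is reproducible and
#' insensitive to generation order.
#'
#' @param config A [simulation_config()].
#' @param reference Optional pre-built `toy_reference`; built from
#'   `config` when `NULL`.
#' @return List with `mutations` and `segments` (pooled tables), `labels`
#'   (tibble `sample_id`, `label`), `truth_features` (feature values
#'   implied by the generator's intended tallies, computed without the
#'   classifier), `intended` (per-sample tallies), `reference`, `assay`.
#' @export
simulate_cohort <- function(config = simulation_config(), reference = NULL) {
  if (is.null(reference)) reference <- make_reference(config)
  ids <- c(sprintf("HRD%03d", seq_len(config$n_hrd)),
           sprintf("HRP%03d", seq_len(config$n_hrp)))
  classes <- c(rep("HRD", config$n_hrd), rep("HRP", config$n_hrp))
  seeds <- (config$seed + 100003 * seq_along(ids)) %% 2147483647L
  sims <- purrr::pmap(list(classes, ids, seeds), function(cl, id, sd) {
    simulate_sample(cl, config, reference, id, seed = sd)
  })
  truth <- purrr::map2_dfr(sims, seq_along(sims), function(s, i) {
    sbs_tot <- sum(s$intended$SBS96)
    id_tot <- sum(s$intended$ID83)
    seg_tot <- sum(s$intended$segment_types)
    tibble::tibble(
      sample_id = ids[i], label = classes[i],
      loh_1_40mb = prop0(s$intended$segment_types[["loh_1_40mb"]], seg_tot),
      del5_mh = prop0(sum(s$intended$ID83[DEL5_MH_CHANNELS]), id_tot),
      het_3_9_10_40mb = prop0(s$intended$segment_types[["het_3_9_10_40mb"]], seg_tot),
      ncgt = prop0(sum(s$intended$SBS96[NCGT_CHANNELS]), sbs_tot),
      nctg = prop0(sum(s$intended$SBS96[NCTG_CHANNELS]), sbs_tot),
      het_2_4_gt40mb = prop0(s$intended$segment_types[["het_2_4_gt40mb"]], seg_tot)
    )
  })
  list(
    mutations = dplyr::bind_rows(purrr::map(sims, "mutations")),
    segments = dplyr::bind_rows(purrr::map(sims, "segments")),
    labels = tibble::tibble(sample_id = ids, label = classes),
    truth_features = truth,
    intended = stats::setNames(purrr::map(sims, "intended"), ids),
    reference = reference,
    assay = "WGS"
  )
}

prop0 <- function(num, den) if (den == 0) 0 else as.numeric(num) / den

#' Simulate a six-feature cohort directly (no catalogues)
#'
#' Draws feature vectors from per-class beta/Poisson distributions whose
#' means mirror the catalogue generator's expectations, for fast
#' model-level experiments: HRD means (LOH 0.35, DEL.5.MH 0.30 or a count
#' with mean 10 for WES, HET 3-9 0.20, N[C>G]T 0.25, N[C>T]G 0.05,
#' HET 2-4 0.05) against the HRP means (0.08, 0.03 / mean 1, 0.04, 0.05,
#' 0.25, 0.45).
#'
#' @param n_hrd,n_hrp Samples per arm.
#' @param assay `"WGS"` (DEL.5.MH as a proportion) or `"WES"` (count).
#' @param effect_scale Multiplier in [0, 1] shrinking every HRD-HRP mean
#'   difference towards the pooled mean (0 = no class signal).
#' @param seed Seed.
#' @return Tibble: `sample_id`, `label`, `assay`, six feature columns.
#' @export
simulate_feature_cohort <- function(n_hrd = 100, n_hrp = 100,
                                    assay = c("WGS", "WES"),
                                    effect_scale = 1, seed = 1) {
  assay <- match.arg(assay)
  means <- list(
    HRD = c(loh_1_40mb = 0.35, del5_mh = 0.30, het_3_9_10_40mb = 0.20,
            ncgt = 0.25, nctg = 0.05, het_2_4_gt40mb = 0.05),
    HRP = c(loh_1_40mb = 0.08, del5_mh = 0.03, het_3_9_10_40mb = 0.04,
            ncgt = 0.05, nctg = 0.25, het_2_4_gt40mb = 0.45)
  )
  mid <- (means$HRD + means$HRP) / 2
  means <- lapply(means, function(m) mid + effect_scale * (m - mid))
  kappa <- 60  # beta precision: like estimating a proportion from ~60 events
  with_seed(seed, {
    draw <- function(class, n, prefix) {
      m <- means[[class]]
      f <- vapply(FEATURE_ORDER, function(ft) {
        stats::rbeta(n, m[[ft]] * kappa, (1 - m[[ft]]) * kappa)
      }, numeric(n))
      f <- matrix(f, nrow = n, dimnames = list(NULL, FEATURE_ORDER))
      if (assay == "WES") {
        f[, "del5_mh"] <- stats::rpois(n, m[["del5_mh"]] / 0.03)
      }
      tibble::tibble(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
                     label = class, assay = assay) |>
        dplyr::bind_cols(tibble::as_tibble(f))
    }
    dplyr::bind_rows(draw("HRD", n_hrd, "HRD"), draw("HRP", n_hrp, "HRP"))
  })
}
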