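make_sbs_matrix <- function(counts_by_sample) {
  chans <- sbs96_channels()
  m <- matrix(0L, 96, length(counts_by_sample),
              dimnames = list(chans, names(counts_by_sample)))
  for (s in names(counts_by_sample)) {
    cs <- counts_by_sample[[s]]
    m[names(cs), s] <- as.integer(cs)
  }
  context_matrix(m, "SBS96")
}

test_that("identical groups show no enrichment; label swap negates fold changes", {
  m <- make_sbs_matrix(list(
    a1 = c("A[C>A]A" = 10, "A[C>G]A" = 90), a2 = c("A[C>A]A" = 10, "A[C>G]A" = 90),
    b1 = c("A[C>A]A" = 10, "A[C>G]A" = 90), b2 = c("A[C>A]A" = 10, "A[C>G]A" = 90)
  ))
  labels <- c(a1 = "HRD", a2 = "HRD", b1 = "HRP", b2 = "HRP")
  res <- channel_enrichment(m, labels)
  expect_true(all(res$enriched_in == "none"))
  expect_equal(res$p_value[res$channel == "A[C>A]A"], 1)
  expect_lt(abs(res$log2_fc[res$channel == "A[C>A]A"]), 1e-9)

  # antisymmetry under label swap
  m2 <- make_sbs_matrix(list(
    a1 = c("A[C>A]A" = 40, "A[C>G]A" = 60), a2 = c("A[C>A]A" = 45, "A[C>G]A" = 55),
    b1 = c("A[C>A]A" = 10, "A[C>G]A" = 90), b2 = c("A[C>A]A" = 12, "A[C>G]A" = 88)
  ))
  res_fwd <- channel_enrichment(m2, labels)
  swapped <- c(a1 = "HRP", a2 = "HRP", b1 = "HRD", b2 = "HRD")
  res_rev <- channel_enrichment(m2, swapped)
  nz <- res_fwd$log2_fc != 0 | res_rev$log2_fc != 0
  expect_equal(res_fwd$log2_fc[nz], -res_rev$log2_fc[nz], tolerance = 1e-6)
  expect_equal(res_fwd$p_value, res_rev$p_value)
})

test_that("Fisher p-values equal the hypergeometric tail-sum on the pooled table", {
  withr::with_seed(17, {
    m <- make_sbs_matrix(list(
      h1 = c("A[C>A]A" = 30, "A[C>G]A" = 70), h2 = c("A[C>A]A" = 25, "A[C>G]A" = 60),
      p1 = c("A[C>A]A" = 8, "A[C>G]A" = 90), p2 = c("A[C>A]A" = 12, "A[C>G]A" = 85)
    ))
  })
  labels <- c(h1 = "HRD", h2 = "HRD", p1 = "HRP", p2 = "HRP")
  res <- channel_enrichment(m, labels)
  mm <- unclass(m)
  tot_hrd <- sum(mm[, c("h1", "h2")]); tot_hrp <- sum(mm[, c("p1", "p2")])
  for (ch in c("A[C>A]A", "A[C>G]A")) {
    a <- sum(mm[ch, c("h1", "h2")]); c_ <- sum(mm[ch, c("p1", "p2")])
    expect_equal(res$p_value[res$channel == ch],
                 oracle_fisher_p(a, tot_hrd - a, c_, tot_hrp - c_),
                 tolerance = 1e-12)
  }
})

test_that("a planted enrichment is recovered and flagged in the right group", {
  coh <- test_cohort()
  ref <- test_reference()
  labels <- setNames(coh$labels$label, coh$labels$sample_id)
  sbs <- build_context_matrix(coh$mutations, "SBS96", ref$genome,
                              samples = coh$labels$sample_id)
  res <- channel_enrichment(sbs, labels, fc_threshold = 0.75)
  ncgt <- paste0(c("A", "C", "G", "T"), "[C>G]T")
  nctg <- paste0(c("A", "C", "G", "T"), "[C>T]G")
  # at this cohort size every planted channel clears the fold-change
  # threshold in the right direction ...
  expect_true(all(res$log2_fc[res$channel %in% ncgt] > 0.75))
  expect_true(all(res$log2_fc[res$channel %in% nctg] < -0.75))
  # ... and nothing is ever flagged in the wrong direction
  expect_false(any(res$enriched_in[res$channel %in% ncgt] == "HRP"))
  expect_false(any(res$enriched_in[res$channel %in% nctg] == "HRD"))
  expect_true(all(res$enriched_in[!res$channel %in% c(ncgt, nctg)] == "none"))
  # q-values are BH-monotone relative to p-values
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("zero-event groups and unlabeled columns are errors", {
  m <- make_sbs_matrix(list(a = c("A[C>A]A" = 5), b = c("A[C>A]A" = 5)))
  expect_error(channel_enrichment(m, c(a = "HRD", b = "HRD")), "non-empty")
  zero <- make_sbs_matrix(list(a = c("A[C>A]A" = 5), b = integer()))
  expect_error(channel_enrichment(zero, c(a = "HRD", b = "HRP")), "zero total")
  expect_error(channel_enrichment(m, c(a = "HRD")), "label")
})

test_that("feature extraction computes the documented ratios", {
  sbs <- make_sbs_matrix(list(S1 = c("A[C>T]G" = 7, "A[C>A]A" = 3)))
  id_m <- matrix(0L, 83, 1, dimnames = list(id83_channels(), "S1"))
  id_m["5:Del:M:2", 1] <- 4L
  id_m["1:Del:T:0", 1] <- 6L
  id <- context_matrix(id_m, "ID83")
  seg <- segment_records(c("S1", "S1"), c("1", "2"), c(1, 1),
                         c(25e6, 60e6), c(1, 1), c(0, 1))
  f_wgs <- extract_features(sbs, id, seg, assay = "WGS")
  expect_equal(f_wgs$nctg, 0.7)
  expect_equal(f_wgs$ncgt, 0)
  expect_equal(f_wgs$del5_mh, 0.4)           # proportion of indel events
  expect_equal(f_wgs$loh_1_40mb, 0.5)
  expect_equal(f_wgs$het_2_4_gt40mb, 0.5)
  expect_equal(f_wgs$het_3_9_10_40mb, 0)
  f_wes <- extract_features(sbs, id, seg, assay = "WES")
  expect_equal(f_wes$del5_mh, 4)             # absolute count for exomes
  expect_equal(f_wes$nctg, 0.7)              # other features unchanged
})

test_that("feature extraction matches a brute-force filter-and-count on a random catalogue", {
  coh <- test_cohort()
  ref <- test_reference()
  ids <- coh$labels$sample_id
  sbs <- build_context_matrix(coh$mutations, "SBS96", ref$genome, samples = ids)
  id <- build_context_matrix(coh$mutations, "ID83", ref$genome, samples = ids)
  feats <- extract_features(sbs, id, coh$segments, assay = "WGS", samples = ids)
  for (s in ids[c(1, 7)]) {
    seg <- coh$segments[coh$segments$sample_id == s, ]
    loh <- 0; het39 <- 0; het24 <- 0
    for (i in seq_len(nrow(seg))) {
      tcn <- seg$major_cn[i] + seg$minor_cn[i]
      sz <- seg$end[i] - seg$start[i] + 1
      if (seg$minor_cn[i] == 0 && tcn >= 1 && sz > 1e6 && sz <= 4e7) loh <- loh + 1
      if (seg$minor_cn[i] >= 1 && tcn >= 3 && tcn <= 9 && sz > 1e7 && sz <= 4e7)
        het39 <- het39 + 1
      if (seg$minor_cn[i] >= 1 && tcn >= 2 && tcn <= 4 && sz > 4e7) het24 <- het24 + 1
    }
    row <- feats[feats$sample_id == s, ]
    expect_equal(row$loh_1_40mb, loh / nrow(seg))
    expect_equal(row$het_3_9_10_40mb, het39 / nrow(seg))
    expect_equal(row$het_2_4_gt40mb, het24 / nrow(seg))
    # CN proportion features are proportions of disjoint subsets
    expect_lte(row$loh_1_40mb + row$het_3_9_10_40mb + row$het_2_4_gt40mb, 1)
  }
})

test_that("feature extraction is invariant to record order and batch splits", {
  coh <- test_cohort()
  ref <- test_reference()
  ids <- coh$labels$sample_id
  build <- function(mut) {
    list(sbs = build_context_matrix(mut, "SBS96", ref$genome, samples = ids),
         id = build_context_matrix(mut, "ID83", ref$genome, samples = ids))
  }
  whole <- build(coh$mutations)
  perm <- withr::with_seed(2, sample(nrow(coh$mutations)))
  shuffled <- build(coh$mutations[perm, ])
  f1 <- extract_features(whole$sbs, whole$id, coh$segments, "WGS", samples = ids)
  f2 <- extract_features(shuffled$sbs, shuffled$id, coh$segments, "WGS",
                         samples = ids)
  expect_equal(f1, f2)
  # batch split: counts from two halves sum to the whole (samples absent
  # from a half legitimately warn about empty columns)
  half <- nrow(coh$mutations) %/% 2
  a <- suppressWarnings(build(coh$mutations[seq_len(half), ]))
  b <- suppressWarnings(build(coh$mutations[(half + 1):nrow(coh$mutations), ]))
  expect_identical(unclass(whole$sbs)[, ids],
                   unclass(a$sbs)[, ids] + unclass(b$sbs)[, ids])
})

test_that("zero denominators yield zero features with a warning", {
  sbs <- make_sbs_matrix(list(S1 = integer()))
  id <- context_matrix(matrix(0L, 83, 1, dimnames = list(id83_channels(), "S1")),
                       "ID83")
  seg <- segment_records(character(), character(), numeric(), numeric(),
                         integer(), integer())
  f <- suppressWarnings(extract_features(sbs, id, seg, "WGS"))
  expect_true(all(f[, c("nctg", "ncgt", "del5_mh", "loh_1_40mb")] == 0))
  w <- capture_warnings(extract_features(sbs, id, seg, "WGS"))
  expect_true(any(grepl("zero", w)))
})
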