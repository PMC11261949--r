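test_that("SBS classification follows the pyrimidine convention", {
  expect_equal(classify_sbs("C", "T", "ACG"), "A[C>T]G")
  expect_equal(classify_sbs("G", "C", "AGT"), "A[C>G]T")
  # all four N[C>T]G / N[C>G]T channels are reachable
  expect_equal(classify_sbs(rep("C", 4), rep("T", 4),
                            paste0(c("A", "C", "G", "T"), "CG")),
               paste0(c("A", "C", "G", "T"), "[C>T]G"))
  # context centre must match ref
  expect_true(is.na(classify_sbs("C", "T", "ATG")))
})

test_that("any SBS and its reverse-complement presentation share a channel", {
  withr::with_seed(5, {
    bases <- c("A", "C", "G", "T")
    for (i in 1:200) {
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
      ctx <- paste0(sample(bases, 1), ref, sample(bases, 1))
      rc <- function(x) chartr("ACGT", "TGCA",
                               paste(rev(strsplit(x, "")[[1]]), collapse = ""))
      expect_equal(classify_sbs(ref, alt, ctx),
                   classify_sbs(rc(ref), rc(alt), rc(ctx)))
    }
  })
})

test_that("microhomology length matches an exhaustive prefix/suffix scan", {
  expect_equal(microhomology_length("TAGGC", "CCCCC", "TAGTT"), 3L)
  expect_equal(microhomology_length("AAAAA", "GCGCG", "AAAAA"), 0L)  # full = repeat
  expect_equal(microhomology_length("GATC", "AAAA", "TTTT"), 0L)
  withr::with_seed(21, {
    for (i in 1:300) {
      L <- sample(2:8, 1)
      s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      f5 <- paste(sample(c("A", "C", "G", "T"), L + 4, TRUE), collapse = "")
      f3 <- paste(sample(c("A", "C", "G", "T"), L + 4, TRUE), collapse = "")
      expect_equal(microhomology_length(s, f5, f3), oracle_mh(s, f5, f3),
                   info = paste(s, f5, f3))
    }
  })
})

test_that("indel channels cover the documented examples", {
  # 7 bp deletion with 2 bp microhomology -> length bin 5+, MH 2
  expect_equal(classify_indel("TGCATCGA", "T", "AAGTCCT", "GCTTAAA"),
               "5:Del:M:2")
  # 1 bp T deletion inside a TTTTTT run -> homopolymer bin 6+
  expect_equal(classify_indel("CT", "C", "AGCCC", "TTTTTAG"), "1:Del:T:5")
  # 3 bp insertion with no flanking copy of the motif
  expect_equal(classify_indel("A", "AGTC", "CCCCA", "GGAAA"), "3:Ins:R:0")
  # deletion inside a repeat tract routes to the repeat channels, never MH
  expect_equal(classify_indel("AACGT", "A", "GGGTA", "ACGTACGTTT"),
               "4:Del:R:2")
})

test_that("randomised indels agree with the brute-force oracle and MH/repeat exclusion holds", {
  withr::with_seed(31, {
    for (i in 1:400) {
      L <- sample(1:8, 1)
      is_del <- runif(1) < 0.6
      s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      anchor <- sample(c("A", "C", "G", "T"), 1)
      f5 <- paste0(paste(sample(c("A", "C", "G", "T"), 6 * L + 4, TRUE),
                         collapse = ""), anchor)
      f3 <- paste(sample(c("A", "C", "G", "T"), 6 * L + 4, TRUE), collapse = "")
      ref <- if (is_del) paste0(anchor, s) else anchor
      alt <- if (is_del) anchor else paste0(anchor, s)
      got <- classify_indel(ref, alt, f5, f3)
      expect_equal(got, oracle_id83(ref, alt, f5, f3),
                   info = paste(ref, alt, f5, f3))
      # a deletion assigned an MH channel never has an adjacent full copy
      if (grepl(":Del:M:", got)) {
        expect_equal(oracle_id83(ref, alt, f5, f3), got)
        expect_false(grepl(":R:", got))
      }
    }
  })
})

test_that("CN examples classify as documented", {
  expect_equal(classify_cn(1, 0, 25e6), "1:LOH:10Mb-40Mb")
  expect_equal(classify_cn(1, 1, 60e6), "2:het:>40Mb")
  expect_equal(classify_cn(0, 0, 5e4), "0:homdel:0-100kb")
  # upper bin edges are inclusive, lower exclusive
  expect_equal(classify_cn(1, 0, 1e7), "1:LOH:1Mb-10Mb")
  expect_equal(classify_cn(1, 0, 1e7 + 1), "1:LOH:10Mb-40Mb")
})

test_that("matrix building conserves events, ignores order, and reports exclusions", {
  genome <- random_genome(2e4)
  withr::with_seed(13, {
    n <- 120
    pos <- sample(100:19000, n)
    ref <- substring(as.character(genome[[1]]), pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    mut <- mutation_records(sample(c("S1", "S2"), n, TRUE), "1", pos, ref, alt)
  })
  m <- build_context_matrix(mut, "SBS96", genome)
  expect_equal(unname(colSums(m)[c("S1", "S2")]),
               unname(as.vector(table(mut$sample_id)[c("S1", "S2")])))
  # order invariance
  perm <- withr::with_seed(3, sample(nrow(mut)))
  m2 <- build_context_matrix(mut[perm, ], "SBS96", genome,
                             samples = colnames(m))
  expect_identical(unclass(m)[, ], unclass(m2)[, ])
  # per-event loop oracle
  for (s in c("S1", "S2")) {
    sub <- mut[mut$sample_id == s, ]
    ctx <- substring(as.character(genome[[1]]), sub$pos - 1, sub$pos + 1)
    chans <- oracle_sbs96(sub$ref, sub$alt, ctx)
    expect_equal(unname(unclass(m)[, s]),
                 unname(as.vector(table(factor(chans, sbs96_channels())))))
  }
})

test_that("a sample with zero classifiable events keeps a zero column with a warning", {
  genome <- random_genome(1e4)
  mut <- mutation_records("S1", "1", 500, substr(as.character(genome[[1]]), 500, 500),
                          setdiff(c("A", "C"), substr(as.character(genome[[1]]), 500, 500))[1])
  expect_warning(
    m <- build_context_matrix(mut, "SBS96", genome, samples = c("S1", "EMPTY")),
    "zero classifiable"
  )
  expect_equal(sum(m[, "EMPTY"]), 0)
  expect_equal(sum(m[, "S1"]), 1)
})
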