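# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

tiny_config <- function(...) {
  simulation_config(seed = 42, n_hrd = 6, n_hrp = 6,
                    sbs_burden = 80, indel_burden = 50, n_segments = 40,
                    seq_length = 1.5e5, ...)
}

test_reference <- function() {
  fixture("reference", function() make_reference(tiny_config()))
}

test_cohort <- function() {
  fixture("cohort", function() simulate_cohort(tiny_config(), test_reference()))
}

# Random genome as a plain string + DNAStringSet, for classifier tests.
random_genome <- function(len = 5e4, seed = 99, chroms = "1") {
  withr::with_seed(seed, {
    seqs <- vapply(chroms, function(cc) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  })
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- chroms
  g
}
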