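# Shared, lazily built test objects (built once per test run).

shared <- new.env()

toy_rotamers <- function() {
  if (is.null(shared$rot)) shared$rot <- make_toy_rotamer_library()
  shared$rot
}

# corpus of 28 defect-free cycles covering lengths 3..30, plus the library
# built from it
corpus28 <- function() {
  if (is.null(shared$corpus28)) {
    dir <- file.path(tempdir(), "cycpepgen-corpus28")
    if (!dir.exists(dir))
      make_fixture_corpus(fixture_spec(28, c(3, 30), seed = 101), dir)
    shared$corpus28 <- read_fixture_corpus(dir)
  }
  shared$corpus28
}

library28 <- function() {
  if (is.null(shared$lib28)) shared$lib28 <- build_library(corpus28()$structures)
  shared$lib28
}

# a single mid-size cyclic structure reused across tests
cycle6 <- function() {
  if (is.null(shared$cycle6)) shared$cycle6 <- make_ideal_cycle(6, seed = 61)
  shared$cycle6
}

# minimal stand-in fragment for template-scoring tests (only the sequence,
# length and resolution fields matter to the scorer)
stub_fragment <- function(sequence, resolution = 2.0) {
  frag <- extract_cyclic_fragments(cycle6())[[1]]
  frag$sequence <- sequence
  frag$length <- nchar(sequence)
  frag$resolution <- resolution
  frag
}
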