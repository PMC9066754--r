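test_that("position-wise BLOSUM62 scores match hand-computed values", {
  expect_equal(sequence_score("CAC", "CAC"), 22)   # 9 + 4 + 9
  expect_equal(sequence_score("CAC", "CGC"), 18)   # 9 + 0 + 9
  expect_error(sequence_score("CAC", "CACA"), class = "cycpep_domain_error")
  expect_error(sequence_score("CAB", "CAC"), class = "cycpep_domain_error")
})

test_that("an identical sequence never scores below any other template", {
  set.seed(20)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    n <- sample(3:12, 1)
    target <- paste(sample(aas, n, replace = TRUE), collapse = "")
    other <- paste(sample(aas, n, replace = TRUE), collapse = "")
    expect_gte(sequence_score(target, target), sequence_score(target, other))
  }
})

test_that("selection probabilities follow the similarity/resolution weighting", {
  # equal scores and resolutions -> uniform
  t1 <- stub_fragment("AAAA", 2.0)
  t2 <- stub_fragment("AAAA", 2.0)
  p <- template_probabilities(list(t1, t2), "AAAA")
  expect_equal(p$probability, c(0.5, 0.5), tolerance = 1e-12)
  # single template -> probability one
  p1 <- template_probabilities(list(t1), "AAAA")
  expect_equal(p1$probability, 1.0)
  # s2 = s_max / 2 at equal resolution -> ratio exp(3) with w_s = 6
  ta <- stub_fragment("AAAAAA", 2.0)   # s = 24 against all-A target
  tb <- stub_fragment("AAAGGG", 2.0)   # s = 12
  p2 <- template_probabilities(list(ta, tb), "AAAAAA")
  expect_equal(p2$probability[1] / p2$probability[2], exp(3), tolerance = 1e-9)
  expect_error(template_probabilities(list(), "AAA"), class = "cycpep_no_template")
})

test_that("probabilities normalize, rise with similarity and fall with resolution", {
  set.seed(21)
  aas <- strsplit("ADEFGHIKLMNQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    target <- paste(sample(aas, n, replace = TRUE), collapse = "")
    tpl <- lapply(1:5, function(i)
      stub_fragment(paste(sample(aas, n, replace = TRUE), collapse = ""),
                    runif(1, 1, 3)))
    p <- template_probabilities(tpl, target)
    expect_equal(sum(p$probability), 1, tolerance = 1e-9)
    expect_true(all(p$probability >= 0))
    # scale invariance in the resolution column
    tpl_scaled <- lapply(tpl, function(f) { f$resolution <- f$resolution * 7.3; f })
    w <- selection_weights(default_resolution = 3 * 7.3)
    p_scaled <- template_probabilities(tpl_scaled, target, w)
    expect_equal(p_scaled$probability, p$probability, tolerance = 1e-9)
  }
  # monotone in s at fixed r
  tpl <- list(stub_fragment("AAAAAA", 2), stub_fragment("AAAAAG", 2),
              stub_fragment("AAAGGG", 2))
  p <- template_probabilities(tpl, "AAAAAA")
  expect_true(all(diff(p$probability) < 0))
  # antitone in r at fixed s
  tpl <- list(stub_fragment("AAAAAA", 1.0), stub_fragment("AAAAAA", 2.0),
              stub_fragment("AAAAAA", 3.0))
  p <- template_probabilities(tpl, "AAAAAA")
  expect_true(all(diff(p$probability) < 0))
})

test_that("an all-negative score column drops the similarity term", {
  tpl <- list(stub_fragment("PPP", 2.0), stub_fragment("GGG", 2.0))
  p <- template_probabilities(tpl, "WWW")   # W/P = -4, W/G = -2: s_max < 0
  expect_equal(p$probability, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("missing resolutions fall back to the declared default", {
  t1 <- stub_fragment("AAAA", NA_real_)
  t2 <- stub_fragment("AAAA", 3.0)
  p <- template_probabilities(list(t1, t2), "AAAA",
                              selection_weights(default_resolution = 3.0))
  expect_equal(p$probability, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("template sampling is categorical, seeded and converging", {
  s1 <- data.frame(template_index = 1L, probability = 1.0)
  expect_true(all(sample_template(s1, 50) == 1L))
  s2 <- data.frame(template_index = 1:2, probability = c(0.5, 0.5))
  set.seed(42)
  draws <- sample_template(s2, 1e5)
  expect_lt(abs(mean(draws == 1) - 0.5), 0.01)
  set.seed(7); a <- sample_template(s2, 100)
  set.seed(7); b <- sample_template(s2, 100)
  expect_identical(a, b)
})

test_that("identity filtering removes templates at or above the cutoff", {
  tpl <- list(stub_fragment("AAAAA"), stub_fragment("AAAAG"),
              stub_fragment("AGGGG"))
  # identities to target AAAAA: 100, 80, 20
  kept <- filter_by_identity(tpl, "AAAAA", 100)
  expect_length(kept, 2)
  kept <- filter_by_identity(tpl, "AAAAA", 80)      # 80.0 >= 80 removed
  expect_length(kept, 1)
  expect_equal(kept[[1]]$sequence, "AGGGG")
  kept <- filter_by_identity(tpl, "AAAAA", 81)      # 80 < 81 kept
  expect_length(kept, 2)
  expect_error(filter_by_identity(tpl, "AAAAA", 10),
               class = "cycpep_no_template")
  expect_equal(percent_identity("AAAAG", "AAAAA"), 80)
})
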