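test_that("the size-dependent success cutoff follows 1 + ln(n/3)", {
  expect_identical(success_cutoff(3), 1.0)
  expect_equal(success_cutoff(30), 1 + log(10), tolerance = 1e-12)
  expect_equal(success_cutoff(8), 1 + log(8 / 3), tolerance = 1e-12)
  v <- success_cutoff(3:30)
  expect_true(all(diff(v) > 0))          # strictly increasing
  expect_true(all(diff(diff(v)) < 0))    # concave
  expect_error(success_cutoff(2), class = "cycpep_domain_error")
  crit <- success_criterion(n0 = 5, coefficient = 2)
  expect_equal(success_cutoff(5, crit), 2.0)
})

test_that("RMSD metrics vanish for self-comparison and rigid motion", {
  set.seed(40)
  s <- make_ideal_cycle(8, seed = 81)
  ens <- generate_ensemble(
    modeling_request(structure_sequence(s), c(1, 8), 1, seed = 2),
    build_library(list(s)), toy_rotamers())
  m <- ens$models[[1]]
  for (sel in c("ca", "backbone", "heavy")) {
    expect_equal(as.numeric(rmsd_metric(m, m, sel)), 0, tolerance = 1e-12)
  }
  moved <- m
  xyz <- random_rigid(as.matrix(m$atoms[, c("x", "y", "z")]))
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
  for (sel in c("ca", "backbone", "heavy"))
    expect_lt(as.numeric(rmsd_metric(m, moved, sel)), 1e-8)
})

test_that("the Calpha metric agrees with direct superposition of extracted coordinates", {
  s <- make_ideal_cycle(8, seed = 82)
  s2 <- make_ideal_cycle(8, seed = 83)
  s2$residues <- s$residues   # same sequence labels, different conformation
  r1 <- as.numeric(rmsd_metric(s2, s, "ca"))
  caA <- as.matrix(s$atoms[s$atoms$atom == "CA", c("x", "y", "z")])
  caB <- as.matrix(s2$atoms[s2$atoms$atom == "CA", c("x", "y", "z")])
  expect_equal(r1, superposed_rmsd(caB, caA), tolerance = 1e-9)
  expect_gt(r1, 0)
})

test_that("incompatible structures are rejected", {
  s6 <- cycle6()
  s8 <- make_ideal_cycle(8, seed = 84)
  expect_error(rmsd_metric(s6, s8), class = "cycpep_domain_error")
})

test_that("ensemble accuracy is the best prefix RMSD and non-increasing in depth", {
  set.seed(41)
  s <- make_ideal_cycle(6, seed = 61, tail_lengths = c(2, 2))
  lib <- build_library(list(s))
  ens <- generate_ensemble(
    modeling_request(structure_sequence(s), c(3, 8), 10, seed = 3),
    lib, toy_rotamers())
  expect_length(ens$models, 10)
  per_model <- vapply(ens$models, function(m)
    as.numeric(rmsd_metric(m, s, "ca")), numeric(1))
  accs <- vapply(1:10, function(k) ensemble_accuracy(ens, s, "ca", top_k = k),
                 numeric(1))
  expect_equal(accs, cummin(per_model), tolerance = 1e-12)
  expect_true(all(diff(accs) <= 0))
  expect_equal(accs[1], per_model[1])
  expect_error(ensemble_accuracy(list(), s, "ca"), class = "cycpep_domain_error")
  expect_error(ensemble_accuracy(ens, s, "ca", top_k = 11),
               class = "cycpep_domain_error")
})

test_that("benchmark reports compute per-bin aggregates and success rates", {
  set.seed(42)
  s <- make_ideal_cycle(6, seed = 61, tail_lengths = c(2, 2))
  lib <- build_library(list(s))
  rot <- toy_rotamers()
  seq10 <- structure_sequence(s)
  ens <- generate_ensemble(modeling_request(seq10, c(3, 8), 5, seed = 4), lib, rot)
  # a surely-successful case: the reference itself leads the ensemble
  xyz <- s$atoms[, c("x", "y", "z")]
  perfect <- ens
  perfect$models <- c(list(structure(list(
    sequence = seq10, disulfide = c(3, 8),
    atoms = data.frame(res_index = s$atoms$res_index, atom = s$atoms$atom,
                       element = s$atoms$element, x = xyz$x, y = xyz$y,
                       z = xyz$z, stringsAsFactors = FALSE),
    provenance = list()), class = "pep_model")), ens$models)
  # a surely-failing case: reference scaled far away from any model
  far <- s
  far$atoms$x <- far$atoms$x * 10
  far$atoms$y <- far$atoms$y * 10
  far$atoms$z <- far$atoms$z * 10
  cases <- list(list(id = "hit", ensemble = perfect, reference = s),
                list(id = "miss", ensemble = ens, reference = far))
  rep1 <- evaluate_benchmark(cases, bins = c(0, 10), top_k = 10)
  expect_equal(rep1$rows$success, c(TRUE, FALSE))
  all_row <- rep1$aggregates[rep1$aggregates$bin == "ALL", ]
  expect_equal(all_row$success_rate, 50.0, tolerance = 1e-9)
  expect_equal(rep1$rows$best_crmsd[1], 0, tolerance = 1e-9)
  # aggregates reproduce an independent pass over the rows
  ok <- rep1$rows[!rep1$rows$failed, ]
  expect_equal(all_row$mean_crmsd, mean(ok$best_crmsd), tolerance = 1e-9)
  expect_equal(all_row$mean_brmsd, mean(ok$best_brmsd), tolerance = 1e-9)
  # a case violating the preconditions is excluded, not fatal
  s8 <- make_ideal_cycle(8, seed = 85)
  cases_bad <- c(cases, list(list(id = "bad", ensemble = ens, reference = s8)))
  rep2 <- evaluate_benchmark(cases_bad, bins = c(0, 10), top_k = 10)
  expect_equal(rep2$n_failed, 1)
  expect_equal(rep2$aggregates[rep2$aggregates$bin == "ALL", ]$n, 2)
  # bins are half-open on the left: a length-10 peptide is in (0,10] ...
  expect_equal(rep1$aggregates[rep1$aggregates$bin == "(0,10]", ]$n, 2)
  # ... but not in (10,20]
  rep3 <- evaluate_benchmark(cases, bins = c(10, 20), top_k = 10)
  expect_equal(rep3$aggregates[rep3$aggregates$bin == "ALL", ]$n, 2)
  expect_false(any(grepl("\\(10,20\\]", rep3$aggregates$bin)))
  # report serialization
  f <- file.path(tempdir(), "report.tsv")
  write_report(rep1, f)
  back <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_equal(nrow(back), 2)
})
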