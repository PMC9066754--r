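test_that("the clustering cutoff follows 0.1*sqrt(n) and its printed endpoints", {
  expect_equal(round(cluster_cutoff(3), 2), 0.17)
  expect_equal(round(cluster_cutoff(30), 2), 0.55)
  expect_equal(cluster_cutoff(16), 0.4)
  expect_true(all(diff(cluster_cutoff(3:30)) > 0))
  expect_error(cluster_cutoff(2), class = "cycpep_domain_error")
  expect_error(cluster_cutoff(31), class = "cycpep_domain_error")
  expect_error(cluster_cutoff(10.5), class = "cycpep_domain_error")
})

test_that("qualifying spans yield exactly one fragment with the right content", {
  s <- cycle6()
  frs <- extract_cyclic_fragments(s)
  expect_length(frs, 1)
  f <- frs[[1]]
  expect_equal(f$length, 6)
  expect_equal(nrow(f$bb), 24)
  expect_equal(substr(f$sequence, 1, 1), "C")
  expect_equal(substr(f$sequence, 6, 6), "C")
  expect_true(all(c("CB", "SG") %in% rownames(f$cys_first)))
  d <- sqrt(sum((f$cys_first["SG", ] - f$cys_last["SG", ])^2))
  expect_lte(d, 2.5)
})

test_that("interior cysteines, overlong spans and missing atoms disqualify", {
  s <- cycle6()
  s2 <- s
  s2$residues$name[3] <- "CYS"
  out <- extract_cyclic_fragments(s2)
  expect_length(out, 0)
  expect_equal(attr(out, "skipped")$reason, "interior_cys")

  s3 <- s
  s3$atoms <- s3$atoms[!(s3$atoms$res_index == 4 & s3$atoms$atom == "O"), ]
  out <- extract_cyclic_fragments(s3)
  expect_length(out, 0)
  expect_equal(attr(out, "skipped")$reason, "incomplete_backbone")

  long <- cycpepgen:::build_fixture_structure(31, c(0, 0), 2.0, "LONG")
  out <- extract_cyclic_fragments(long)
  expect_length(out, 0)
  expect_equal(attr(out, "skipped")$reason, "length")
})

test_that("unmapped nonstandard residues disqualify, mapped ones are renamed", {
  s <- cycle6()
  s$residues$name[4] <- "XYZ"
  s$residues$is_standard[4] <- FALSE
  expect_length(extract_cyclic_fragments(s), 0)
  s$residues$mapped_name[4] <- "SER"
  frs <- extract_cyclic_fragments(s)
  expect_length(frs, 1)
  expect_equal(substr(frs[[1]]$sequence, 4, 4), "S")
})

test_that("greedy clustering groups by backbone RMSD with centroid representatives", {
  f <- extract_cyclic_fragments(cycle6())[[1]]
  cutoff <- cluster_cutoff(6)
  jitter_frag <- function(f, sd, tag) {
    set.seed(nchar(tag) + sd * 1e4)
    f$bb <- f$bb + matrix(rnorm(length(f$bb), 0, sd), nrow(f$bb), 3)
    f$source_pdb <- tag
    f
  }
  a <- jitter_frag(f, 0.001, "AAAA")
  b <- jitter_frag(f, 0.002, "BBBB")
  c_far <- f
  c_far$bb <- f$bb * 1.8          # gross shape change, far beyond the cutoff
  c_far$source_pdb <- "CCCC"
  expect_gt(cycpepgen:::fragment_brmsd(a, c_far), 10 * cutoff)

  cl <- cluster_fragments(list(a, b, c_far), cutoff)
  sizes <- sort(vapply(cl, function(x) length(x$members), integer(1)))
  expect_equal(sizes, c(1L, 2L))

  # identical fragments cluster together; representative is a member
  cl2 <- cluster_fragments(list(f, f), cutoff)
  expect_length(cl2, 1)
  expect_equal(length(cl2[[1]]$members), 2)

  # three-fragment centroid agrees with a brute-force all-pairs computation
  d <- jitter_frag(f, 0.0015, "DDDD")
  trio <- list(a, b, d)
  cl3 <- cluster_fragments(trio, cutoff)
  expect_length(cl3, 1)
  sums <- vapply(seq_along(trio), function(i)
    sum(vapply(seq_along(trio), function(j)
      if (i == j) 0 else cycpepgen:::fragment_brmsd(trio[[i]], trio[[j]]),
      numeric(1))), numeric(1))
  best <- trio[[which.min(sums)]]
  expect_equal(cl3[[1]]$representative$source_pdb, best$source_pdb)
})

test_that("re-clustering representatives yields all singletons", {
  lib <- library28()
  for (len in c("6", "12", "20")) {
    cls <- lib$sub_libraries[[len]]
    if (is.null(cls)) next
    reps <- lapply(cls, function(cl) cl$representative)
    recl <- cluster_fragments(reps, cluster_cutoff(as.integer(len)))
    expect_equal(length(recl), length(reps))
  }
})

test_that("mixed-length clustering input is rejected", {
  f6 <- extract_cyclic_fragments(cycle6())[[1]]
  f8 <- extract_cyclic_fragments(make_ideal_cycle(8, seed = 8))[[1]]
  expect_error(cluster_fragments(list(f6, f8), 0.3), class = "cycpep_domain_error")
  expect_error(cluster_fragments(list(f6), -1), class = "cycpep_domain_error")
})

test_that("library build stratifies by length and skips disqualified input", {
  lib <- library28()
  expect_s3_class(lib, "backbone_library")
  expect_equal(sort(as.integer(names(lib$sub_libraries))), 3:30)
  expect_length(lib$sub_libraries, 28)
  # single-length input -> single sub-library
  lib1 <- build_library(list(cycle6()))
  expect_equal(names(lib1$sub_libraries), "6")
  # a defective-only corpus contributes nothing
  s3 <- cycle6()
  s3$atoms <- s3$atoms[!(s3$atoms$res_index == 4 & s3$atoms$atom == "O"), ]
  expect_warning(lib0 <- build_library(list(s3)), "no qualifying")
  expect_length(lib0$sub_libraries, 0)
})

test_that("library save/load round trip preserves representatives and metadata", {
  lib <- build_library(list(cycle6(), make_ideal_cycle(8, seed = 8)))
  path <- file.path(tempdir(), "cycpepgen-libtest")
  unlink(path, recursive = TRUE)
  save_library(lib, path)
  lib2 <- load_library(path)
  expect_equal(sort(names(lib2$sub_libraries)), sort(names(lib$sub_libraries)))
  for (len in names(lib$sub_libraries)) {
    r1 <- sub_library(lib, as.integer(len))
    r2 <- sub_library(lib2, as.integer(len))
    expect_equal(length(r1), length(r2))
    expect_lt(max(abs(r1[[1]]$bb - r2[[1]]$bb)), 0.001 + 1e-9)
    expect_equal(r1[[1]]$sequence, r2[[1]]$sequence)
    expect_equal(r1[[1]]$resolution, r2[[1]]$resolution, tolerance = 1e-9)
  }
})

test_that("library loading reports corrupt or incomplete directories", {
  empty <- file.path(tempdir(), "cycpepgen-empty")
  dir.create(empty, showWarnings = FALSE)
  expect_error(load_library(empty), class = "cycpep_load_error")

  path <- file.path(tempdir(), "cycpepgen-libtest2")
  unlink(path, recursive = TRUE)
  save_library(build_library(list(cycle6())), path)
  pdbs <- list.files(path, pattern = "\\.pdb$", full.names = TRUE)
  file.remove(pdbs[1])
  err <- tryCatch(load_library(path), error = function(e) e)
  expect_s3_class(err, "cycpep_load_error")
  expect_match(conditionMessage(err), basename(pdbs[1]))
})
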