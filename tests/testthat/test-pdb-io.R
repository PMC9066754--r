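test_that("a complete synthetic chain parses with full backbones", {
  s <- cycle6()
  expect_s3_class(s, "pep_structure")
  expect_equal(nrow(s$residues), 6)
  expect_true(all(backbone_complete(s)))
  expect_equal(substr(structure_sequence(s), 1, 1), "C")
})

test_that("a missing backbone oxygen is reported as incomplete", {
  s <- cycle6()
  s$atoms <- s$atoms[!(s$atoms$res_index == 3 & s$atoms$atom == "O"), ]
  bc <- backbone_complete(s)
  expect_false(bc[3])
  expect_true(all(bc[-3]))
})

test_that("REMARK 2 resolution is read back from the header", {
  s <- make_ideal_cycle(5, seed = 3, resolution = 1.50)
  s2 <- parse_structure(write_structure(s), "A")
  expect_equal(s2$resolution, 1.50)
  s$resolution <- NA_real_
  s3 <- parse_structure(write_structure(s), "A")
  expect_true(is.na(s3$resolution))
})

test_that("malformed records and absent chains raise informative errors", {
  txt <- write_structure(cycle6())
  bad <- sub("^(ATOM  .{24}).{8}", "\\1  xx.yyy ", txt[5])
  txt_bad <- txt; txt_bad[5] <- bad
  err <- tryCatch(parse_structure(txt_bad, "A"), error = function(e) e)
  expect_s3_class(err, "cycpep_parse_error")
  expect_match(conditionMessage(err), "line 5")
  expect_error(parse_structure(txt, "Z"), class = "cycpep_not_found")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.60  0.00           C",
    "ATOM      4  CB AALA A   1       2.000   1.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1       2.100   1.100   0.000  0.50  0.00           C",
    "ATOM      6  C   ALA A   1       2.009   1.075   0.000  1.00  0.00           C",
    "ATOM      7  O   ALA A   1       3.000   1.500   1.000  1.00  0.00           O",
    "END")
  s <- parse_structure(lines, "A")
  a <- s$atoms
  expect_equal(sum(a$atom == "CA"), 1)
  expect_equal(a$x[a$atom == "CA"], 1.500)      # occupancy 0.60 wins
  expect_equal(a$x[a$atom == "CB"], 2.000)      # tie -> altloc A
})

test_that("MODRES annotations map modified residues to their parent", {
  lines <- c(
    "MODRES XXXX SEP A    2  SER  PHOSPHOSERINE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.075   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       3.000   1.500   1.000  1.00  0.00           O",
    "HETATM    5  N   SEP A   2       3.000   1.200   0.000  1.00  0.00           N",
    "HETATM    6  CA  SEP A   2       4.458   1.200   0.000  1.00  0.00           C",
    "HETATM    7  C   SEP A   2       5.009   2.275   0.000  1.00  0.00           C",
    "HETATM    8  O   SEP A   2       6.000   2.700   1.000  1.00  0.00           O",
    "END")
  s <- parse_structure(lines, "A")
  expect_true(s$residues$is_standard[1])
  expect_false(s$residues$is_standard[2])
  expect_equal(s$residues$mapped_name[2], "SER")
  expect_equal(structure_sequence(s), "AS")
})

test_that("disulfide detection pairs bonded cysteines and only them", {
  s <- cycle6()
  s$ssbond <- list()                       # force pure distance detection
  pairs <- detect_disulfides(s)
  expect_equal(pairs, list(c(1L, 6L)))
  # move one SG far away: no pair
  w <- which(s$atoms$res_index == 6 & s$atoms$atom == "SG")
  s2 <- s; s2$atoms$x[w] <- s2$atoms$x[w] + 50
  expect_equal(detect_disulfides(s2), list())
  # no cysteines at all
  s3 <- s
  s3$residues$name <- rep("ALA", 6)
  expect_equal(detect_disulfides(s3), list())
})

test_that("disulfide detection is invariant under rigid motion", {
  set.seed(10)
  s <- cycle6()
  s$ssbond <- list()
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  moved <- random_rigid(xyz)
  s2 <- s
  s2$atoms$x <- moved[, 1]; s2$atoms$y <- moved[, 2]; s2$atoms$z <- moved[, 3]
  expect_equal(detect_disulfides(s2), detect_disulfides(s))
  # every returned pair satisfies the distance bound
  for (p in detect_disulfides(s)) {
    sg1 <- s$atoms[s$atoms$res_index == p[1] & s$atoms$atom == "SG", c("x", "y", "z")]
    sg2 <- s$atoms[s$atoms$res_index == p[2] & s$atoms$atom == "SG", c("x", "y", "z")]
    expect_lte(sqrt(sum((sg1 - sg2)^2)), 2.5)
  }
})

test_that("write/parse round trip preserves structure to 0.001 Angstrom", {
  s <- cycle6()
  s2 <- parse_structure(write_structure(s), "A")
  expect_equal(s2$residues$name, s$residues$name)
  expect_equal(s2$residues$seq_id, s$residues$seq_id)
  expect_equal(s2$atoms$atom, s$atoms$atom)
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                    as.matrix(s$atoms[, c("x", "y", "z")]))), 0.001 + 1e-9)
  # SSBOND record present and referencing the bonded residues
  txt <- write_structure(s)
  ss <- grep("^SSBOND", txt, value = TRUE)
  expect_length(ss, 1)
  expect_match(ss, "CYS A    1.*CYS A    6")
})

test_that("oversized atom names are rejected on write", {
  s <- cycle6()
  s$atoms$atom[1] <- "ABCDE"
  expect_error(write_structure(s), class = "cycpep_format_error")
})
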