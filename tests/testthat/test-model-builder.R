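test_that("modeling requests validate sequence and disulfide positions", {
  expect_s3_class(modeling_request("CAAAC", c(1, 5), 10), "modeling_request")
  expect_error(modeling_request("CAAAC", c(1, 4), 10), "point at 'C'")
  expect_error(modeling_request("CCAAAA", c(1, 2), 10), "cyclic span")
  expect_error(modeling_request("CC", c(1, 2), 10), "length")
})

test_that("the cyclic part copies the template and dresses interior residues", {
  set.seed(30)
  tmpl <- extract_cyclic_fragments(make_ideal_cycle(8, seed = 88))[[1]]
  rot <- toy_rotamers()
  # all-glycine interior: backbone plus the two cysteine side chains only
  m <- build_cyclic_part(tmpl, "CGGGGGGC", rot)
  expect_false(is.null(m))
  sc <- m$atoms[!m$atoms$atom %in% c("N", "CA", "C", "O"), ]
  expect_setequal(unique(sc$res_index), c(1, 8))
  expect_setequal(sc$atom, c("CB", "SG"))
  # backbone equals the template exactly
  expect_equal(cycpepgen:::model_backbone_matrix(m), unname(tmpl$bb),
               ignore_attr = TRUE, tolerance = 1e-12)
  # disulfide geometry copied verbatim
  d_model <- sqrt(sum((cycpepgen:::model_atom_coord(m, 1, "SG") -
                       cycpepgen:::model_atom_coord(m, 8, "SG"))^2))
  d_tmpl <- sqrt(sum((tmpl$cys_first["SG", ] - tmpl$cys_last["SG", ])^2))
  expect_equal(d_model, d_tmpl, tolerance = 1e-6)
  # interior residues of a mixed sequence get complete side chains
  m2 <- build_cyclic_part(tmpl, "CAKLSEWC", rot)
  expect_false(is.null(m2))
  for (k in 2:7) {
    res3 <- aa_one_to_three(substr("CAKLSEWC", k, k))
    have <- m2$atoms$atom[m2$atoms$res_index == k]
    expect_setequal(have, c("N", "CA", "C", "O", sidechain_atom_names(res3)))
  }
  expect_error(build_cyclic_part(tmpl, "CAAC", rot), class = "cycpep_domain_error")
})

test_that("residue growth is append-only with ideal geometry and exact torsion recovery", {
  set.seed(31)
  tmpl <- extract_cyclic_fragments(make_ideal_cycle(6, seed = 66))[[1]]
  rot <- toy_rotamers()
  m <- build_cyclic_part(tmpl, "CAGSAC", rot)
  m$atoms$res_index <- m$atoms$res_index + 1
  m$sequence <- "KCAGSACLV"
  m$disulfide <- c(2, 7)
  before <- m$atoms
  m2 <- expect_no_error(extend_residue(m, 1, "N", rot))
  expect_false(is.null(m2))
  # pre-existing coordinates untouched
  expect_equal(m2$atoms[seq_len(nrow(before)), ], before)
  # ideal peptide bond at the junction
  cN <- cycpepgen:::model_atom_coord(m2, 1, "C")
  nN <- cycpepgen:::model_atom_coord(m2, 2, "N")
  expect_equal(sqrt(sum((cN - nN)^2)), 1.329, tolerance = 1e-6)
  # C-terminal growth
  m3 <- extend_residue(m2, 8, "C", rot)
  expect_false(is.null(m3))
  cC <- cycpepgen:::model_atom_coord(m3, 7, "C")
  nC <- cycpepgen:::model_atom_coord(m3, 8, "N")
  expect_equal(sqrt(sum((cC - nC)^2)), 1.329, tolerance = 1e-6)
  # drawn dihedrals are recoverable from the placed coordinates
  dih <- attr(m3, "dihedrals")
  phi_re <- dihedral(cC, nC,
                     cycpepgen:::model_atom_coord(m3, 8, "CA"),
                     cycpepgen:::model_atom_coord(m3, 8, "C"))
  expect_equal(((phi_re - dih["phi"] + 180) %% 360) - 180, 0,
               ignore_attr = TRUE, tolerance = 1e-4)
  psi_re <- dihedral(nC,
                     cycpepgen:::model_atom_coord(m3, 8, "CA"),
                     cycpepgen:::model_atom_coord(m3, 8, "C"),
                     cycpepgen:::model_atom_coord(m3, 8, "O")) - 180
  expect_equal(((psi_re - dih["psi"] + 180) %% 360) - 180, 0,
               ignore_attr = TRUE, tolerance = 1e-4)
})

test_that("the diversity filter discards near-duplicates and keeps the boundary", {
  set.seed(32)
  tmpl <- extract_cyclic_fragments(make_ideal_cycle(6, seed = 66))[[1]]
  m <- build_cyclic_part(tmpl, "CGGGGC", toy_rotamers())
  expect_true(diversity_accept(m, list()))
  # rigid copy: backbone RMSD zero -> rejected
  m_copy <- m
  xyz <- random_rigid(as.matrix(m$atoms[, c("x", "y", "z")]))
  m_copy$atoms$x <- xyz[, 1]; m_copy$atoms$y <- xyz[, 2]; m_copy$atoms$z <- xyz[, 3]
  expect_false(diversity_accept(m_copy, list(m)))
  # candidate whose superposed backbone RMSD is exactly at the cutoff: kept
  bbm <- cycpepgen:::model_backbone_matrix(m)
  set.seed(33)
  D <- matrix(rnorm(length(bbm)), nrow(bbm), 3)
  f <- function(t) {
    cand <- m
    moved <- bbm + t * D
    k <- 1
    for (i in seq_len(nrow(cand$atoms))) {
      if (cand$atoms$atom[i] %in% c("N", "CA", "C", "O")) {
        cand$atoms$x[i] <- moved[k, 1]; cand$atoms$y[i] <- moved[k, 2]
        cand$atoms$z[i] <- moved[k, 3]; k <- k + 1
      }
    }
    cand
  }
  rms_at <- function(t) superposed_rmsd(bbm, cycpepgen:::model_backbone_matrix(f(t)))
  t_star <- stats::uniroot(function(t) rms_at(t) - 1.0, c(0, 2), tol = 1e-12)$root
  cand <- f(t_star)
  r <- superposed_rmsd(bbm, cycpepgen:::model_backbone_matrix(cand))
  expect_equal(r, 1.0, tolerance = 1e-9)
  expect_equal(diversity_accept(cand, list(m)), r >= 1.0)
  expect_false(diversity_accept(f(t_star * 0.5), list(m)))
  expect_true(diversity_accept(f(t_star * 2), list(m)))
})

test_that("ensembles satisfy every structural and diversity invariant", {
  lib <- library28()
  rot <- toy_rotamers()
  req <- modeling_request("ALCAGKSEWTRCVFQ", c(3, 12), n_models = 8, seed = 424)
  ens <- generate_ensemble(req, lib, rot)
  expect_s3_class(ens, "pep_ensemble")
  expect_length(ens$models, 8)
  for (m in ens$models) {
    expect_length(check_model(m), 0)
    # cyclic-part backbone is bit-identical to a library representative
    tmpl <- sub_library(lib, 10)[[m$provenance$template_index]]
    cyc_bb <- do.call(rbind, lapply(3:12, function(i)
      do.call(rbind, lapply(c("N", "CA", "C", "O"), function(nm)
        cycpepgen:::model_atom_coord(m, i, nm)))))
    expect_identical(unname(cyc_bb), unname(tmpl$bb))
  }
  bbs <- lapply(ens$models, cycpepgen:::model_backbone_matrix)
  for (a in seq_len(length(bbs) - 1)) for (b in (a + 1):length(bbs))
    expect_gte(superposed_rmsd(bbs[[a]], bbs[[b]]), 1.0)
})

test_that("generation is seed-reproducible and honors edge cases", {
  lib <- library28()
  rot <- toy_rotamers()
  req <- modeling_request("ALCAGKSECVF", c(3, 9), n_models = 3, seed = 77)
  e1 <- generate_ensemble(req, lib, rot)
  e2 <- generate_ensemble(req, lib, rot)
  expect_length(e1$models, 3)
  expect_equal(length(e1$models), length(e2$models))
  for (k in seq_along(e1$models))
    expect_identical(e1$models[[k]]$atoms, e2$models[[k]]$atoms)
  # zero requested models -> empty ensemble, no error
  e0 <- generate_ensemble(modeling_request("ALCAGKSECVF", c(3, 9), 0, 1), lib, rot)
  expect_length(e0$models, 0)
  # no sub-library for the cyclic length
  small <- build_library(list(make_ideal_cycle(6, seed = 6)))
  expect_error(generate_ensemble(modeling_request("CAAAAAAC", c(1, 8), 2, 1),
                                 small, rot),
               class = "cycpep_no_template")
})

test_that("ensembles serialize to single- and multi-model PDB layouts", {
  lib <- library28()
  # tails on both sides give the diversity filter room for several models
  req <- modeling_request("ACAGSACV", c(2, 7), n_models = 2, seed = 5)
  ens <- generate_ensemble(req, lib, toy_rotamers())
  expect_length(ens$models, 2)
  d1 <- file.path(tempdir(), "ens-single")
  files <- write_ensemble(ens, d1)
  expect_length(files, 2)
  back <- parse_structure(readLines(files[1]), "A")
  expect_equal(nrow(back$residues), 8)
  d2 <- file.path(tempdir(), "ens-multi")
  f <- write_ensemble(ens, d2, multi_model = TRUE)
  txt <- readLines(f)
  expect_equal(sum(grepl("^MODEL", txt)), 2)
  expect_equal(sum(grepl("^ENDMDL", txt)), 2)
})
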