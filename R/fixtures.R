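# Synthetic structure generator: geometrically valid disulfide-closed cyclic
# peptides (plus optional tails and injected defects) so the entire pipeline
# can be built and tested without any external structure data.
#
# Construction: the cyclic span is an ideal-geometry backbone chain built in
# internal coordinates with uniform (phi, psi) torsions chosen (per length,
# by numerical solution of the discrete-helix closure condition) so the two
# terminal Calphas come within disulfide-bridging distance; per-residue
# torsion jitter provides seeded variability, and the terminal cysteines get
# CB/SG positions solving the SG-SG ~ 2.05 A closure exactly.  Deliberately
# crude compared to real loop geometry, but it satisfies every invariant the
# pipeline checks: complete backbones, valid peptide bonds, disulfide
# closure, no steric clashes.

FIXTURE_AA <- setdiff(AA1, c("C", "G", "P"))  # interior ring residue alphabet

# Uniform (phi, psi) pairs that bring CA_1 and CA_n of an n-residue
# ideal-geometry chain to disulfide-bridging distance.  Solved once per
# length with Nelder-Mead from a fixed grid of starts and cached.
ring_cache <- new.env(parent = emptyenv())

# expand a period-2 torsion pattern c(phi1, psi1, phi2, psi2) to n residues
pattern_torsions <- function(p, n) {
  list(phi = rep(c(p[1], p[3]), length.out = n),
       psi = rep(c(p[2], p[4]), length.out = n))
}

pattern_chain <- function(p, n) {
  tp <- pattern_torsions(p, n)
  build_ring_chain(n, tp$phi, tp$psi)
}

# end-to-end Calpha distance and steric health of a pattern chain,
# including the carbonyl oxygens and the torsion-independent contacts
# between the two chain ends
pattern_geometry <- function(p, n) {
  g <- IDEAL_GEOM
  co <- pattern_chain(p, n)
  for (k in seq_len(n - 1))
    co[[k]]$O <- place_atom(co[[k + 1]]$N, co[[k]]$CA, co[[k]]$C,
                            g$b_c_o, g$a_ca_c_o, 180)
  xyz <- do.call(rbind, lapply(co, function(r) rbind(r$N, r$CA, r$C)))
  resid <- rep(seq_len(n), each = 3)
  dm <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(resid, resid, "-"))
  nonlocal <- dm[sep >= 2 & sep < n - 1]
  # oxygens against everything two or more residues away, and against the
  # following residue's oxygen (eclipsed consecutive carbonyls)
  oxy <- do.call(rbind, lapply(seq_len(n - 1), function(k) co[[k]]$O))
  min_o <- Inf
  for (k in seq_len(n - 1)) {
    far <- abs(resid - k) >= 2
    if (any(far))
      min_o <- min(min_o, sqrt(min(rowSums(sweep(xyz[far, , drop = FALSE],
                                                 2, co[[k]]$O)^2))))
    if (k < n - 1) min_o <- min(min_o, vnorm(co[[k]]$O - co[[k + 1]]$O))
  }
  # contacts between the chain ends that no terminal rotation can relieve
  end1 <- rbind(co[[1]]$CA, co[[1]]$C, co[[1]]$O)
  endn <- rbind(co[[n]]$N, co[[n]]$CA)
  min_cross <- min(sqrt(outer(rowSums(end1^2), rowSums(endn^2), "+") -
                          2 * end1 %*% t(endn)))
  list(d_end = vnorm(co[[n]]$CA - co[[1]]$CA),
       min_nonlocal = if (length(nonlocal) > 0) min(nonlocal) else Inf,
       min_o = min_o, min_cross = min_cross)
}

#' Solve ring-closure torsion patterns for a cyclic span
#'
#' Finds period-2 backbone torsion patterns (phi1, psi1, phi2, psi2) whose
#' ideal-geometry chain of `n` residues is self-avoiding and brings the two
#' terminal Calpha atoms to disulfide-bridging distance.  Patterns are found
#' by Nelder-Mead minimization of two closure formulations (a direct
#' end-distance target, and the discrete-helix screw condition: twist
#' 2*pi*2/n per two-residue unit with zero rise) from a deterministic grid of
#' starts.  The generator ships a precomputed table for all lengths; this
#' solver regenerates it.
#'
#' @param n span length (>= 3).
#' @param max_solutions stop after this many validated patterns.
#' @param gap target Calpha-Calpha distance between the span's two ends
#'   (Angstrom); bridged by the disulfide, so wider than a bonded pair.
#' @return Matrix with columns phi1, psi1, phi2, psi2, one row per pattern.
#' @export
solve_ring_torsions <- function(n, max_solutions = 6, gap = 4.8) {
  # flat-ring twist per residue leaving the requested end gap open:
  # solve theta = (2*pi - 2*asin(gap/(2*r))) / (n - 1) with
  # r = 3.8 / (2*sin(theta/2)) by fixed-point iteration
  theta <- 2 * pi / n
  for (it in 1:40) {
    r <- 3.8 / (2 * sin(theta / 2))
    delta <- 2 * asin(min(1, gap / (2 * r)))
    theta <- (2 * pi - delta) / (n - 1)
  }
  theta_star <- 2 * theta   # per two-residue unit
  theta_star <- min(theta_star, 2 * pi - theta_star)
  unit_screw <- function(p) {
    co <- pattern_chain(p, 4)
    t1 <- rbind(co[[1]]$N, co[[1]]$CA, co[[1]]$C)
    t3 <- rbind(co[[3]]$N, co[[3]]$CA, co[[3]]$C)
    sp <- superpose(t3, t1)
    R <- sp$rotation
    theta <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
    ev <- eigen(R)
    k <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, k]); axis <- axis / vnorm(axis)
    c(theta = theta, rise = abs(sum(sp$translation * axis)))
  }
  obj_screw <- function(p) {
    s <- unit_screw(p)
    sqrt((3.8 * (s["theta"] - theta_star))^2 + s["rise"]^2)
  }
  obj_dist <- function(p) abs(pattern_geometry(p, n)$d_end - gap)
  ok_pattern <- function(p) {
    geo <- pattern_geometry(p, n)
    geo$min_nonlocal >= 2.9 && geo$d_end >= 4.0 && geo$d_end <= 5.8 &&
      geo$min_o >= 2.5 && geo$min_cross >= 2.7
  }
  starts <- as.matrix(expand.grid(phi1 = c(-120, -60, 60, 120),
                                  psi1 = c(-120, -30, 60, 150),
                                  phi2 = c(-90, 0, 90),
                                  psi2 = c(-120, 0, 120)))
  sols <- list()
  for (obj in if (n <= 7) list(obj_dist) else list(obj_screw, obj_dist)) {
    vals <- apply(starts, 1, obj)
    for (o1 in order(vals)[seq_len(30)]) {
      o <- stats::optim(starts[o1, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 350))
      if (o$value > 0.15) next
      p <- (as.numeric(o$par) + 180) %% 360 - 180
      dup <- any(vapply(sols, function(q) max(abs(q - p)) < 10, logical(1)))
      if (dup || !ok_pattern(p)) next
      sols[[length(sols) + 1]] <- p
      if (length(sols) >= max_solutions) break
    }
    if (length(sols) >= max_solutions) break
  }
  if (length(sols) == 0) stop("no ring torsion solution found for length ", n)
  do.call(rbind, sols)
}

# Precomputed ring-closure torsion patterns (see R/ring-torsions.R, built
# with solve_ring_torsions()).
ring_phipsi_solutions <- function(n) {
  key <- as.character(n)
  if (!is.null(ring_cache[[key]])) return(ring_cache[[key]])
  sols <- if (key %in% names(RING_TORSION_TABLE)) RING_TORSION_TABLE[[key]]
          else solve_ring_torsions(n)
  ring_cache[[key]] <- sols
  sols
}

# ideal-geometry backbone chain (N, CA, C per residue) from per-residue
# phi/psi, omega fixed trans
build_ring_chain <- function(n, phi, psi) {
  g <- IDEAL_GEOM
  cb <- canonical_backbone()
  co <- vector("list", n)
  co[[1]] <- list(N = cb$N, CA = cb$CA, C = cb$C)
  for (i in seq_len(n - 1)) {
    prev <- co[[i]]
    Nn <- place_atom(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, psi[i])
    CAn <- place_atom(prev$CA, prev$C, Nn, g$b_n_ca, g$a_c_n_ca, 180)
    Cn <- place_atom(prev$C, Nn, CAn, g$b_ca_c, g$a_n_ca_c, phi[i + 1])
    co[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  co
}

# one construction attempt for a cyclic span of n residues; NULL on failure
build_cycle_once <- function(n, sequence3, pattern = NULL) {
  g <- IDEAL_GEOM
  base <- if (!is.null(pattern)) pattern else {
    sols <- ring_phipsi_solutions(n)
    sols[sample.int(nrow(sols), 1), ]
  }
  tp <- pattern_torsions(base, n)
  phi <- tp$phi + stats::rnorm(n, 0, 5)
  psi <- tp$psi + stats::rnorm(n, 0, 5)
  coords <- build_ring_chain(n, phi, psi)
  # carbonyl oxygens anti to the next residue's nitrogen (independent of the
  # terminal-residue adjustments below)
  for (k in seq_len(n - 1))
    coords[[k]]$O <- place_atom(coords[[k + 1]]$N, coords[[k]]$CA,
                                coords[[k]]$C, g$b_c_o, g$a_ca_c_o, 180)

  # The terminal residues keep two free rotations: N_1 about the CA_1-C_1
  # axis and C_n about the N_n-CA_n axis.  Scan both to pull the loose chain
  # ends (and with them CB_1/CB_n, placed off these atoms) away from the
  # opposite terminus.
  others <- do.call(rbind, lapply(2:(n - 1), function(i)
    do.call(rbind, coords[[i]][c("N", "CA", "C", "O")])))
  clearance <- function(x, ref) min(sqrt(rowSums(sweep(ref, 2, x)^2)))
  taus <- sample(seq(-165, 165, by = 30))
  combos <- expand.grid(t1 = taus, tn = taus)
  combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
  centroid <- colMeans(do.call(rbind, lapply(coords, `[[`, "CA")))
  for (ci in seq_len(min(nrow(combos), 60))) {
    N1 <- place_atom(coords[[2]]$N, coords[[1]]$C, coords[[1]]$CA,
                     g$b_n_ca, g$a_n_ca_c, combos$t1[ci])
    Cn <- place_atom(coords[[n - 1]]$C, coords[[n]]$N, coords[[n]]$CA,
                     g$b_ca_c, g$a_n_ca_c, combos$tn[ci])
    end1 <- rbind(coords[[1]]$CA, coords[[1]]$C, coords[[1]]$O, N1)
    endn <- rbind(coords[[n]]$N, coords[[n]]$CA, Cn)
    # cheap pre-filter: chain ends clear each other and the ring body
    if (min(as.matrix(stats::dist(rbind(end1, endn)))[1:4, 5:7]) < 2.35) next
    if (clearance(N1, others) < 2.35 || clearance(Cn, others) < 2.35) next
    coords[[1]]$N <- N1
    coords[[n]]$C <- Cn
    m <- close_cycle_sidechains(coords, n, sequence3, centroid, g)
    if (!is.null(m)) return(m)
  }
  NULL
}

# place terminal-cysteine CB/SG and the last carbonyl O onto an adjusted
# ring backbone; returns a validated model or NULL
close_cycle_sidechains <- function(coords, n, sequence3, centroid, g) {
  # flat matrix of backbone atoms for cheap steric pre-screens (the last
  # residue's O is placed later, once the disulfide geometry is known)
  atoms_of <- function(i) intersect(BACKBONE_ATOMS, names(coords[[i]]))
  bb_xyz <- do.call(rbind, lapply(seq_len(n), function(i)
    do.call(rbind, coords[[i]][atoms_of(i)])))
  bb_res <- unlist(lapply(seq_len(n), function(i) rep(i, length(atoms_of(i)))))
  bb_atom <- unlist(lapply(seq_len(n), atoms_of))
  min_to <- function(x, keep) {
    if (!any(keep)) return(Inf)
    min(sqrt(rowSums(sweep(bb_xyz[keep, , drop = FALSE], 2, x)^2)))
  }
  base_rows <- NULL

  # terminal cysteine side chains closing the disulfide
  for (signs in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    cb1 <- place_atom(coords[[1]]$N, coords[[1]]$C, coords[[1]]$CA,
                      1.53, 110.1, signs[1] * 122.6)
    cbn <- place_atom(coords[[n]]$N, coords[[n]]$C, coords[[n]]$CA,
                      1.53, 110.1, signs[2] * 122.6)
    d <- vnorm(cbn - cb1)
    if (d > 5.55 || d < 2.6) next
    # CB pre-screen: clear of everything but its own N/CA/C (<= 2 bonds)
    if (min_to(cb1, !(bb_res == 1 & bb_atom != "O")) < 2.25) next
    if (min_to(cbn, !(bb_res == n & bb_atom != "O")) < 2.25) next
    u <- vunit(cbn - cb1)
    w0 <- (cb1 + cbn) / 2 - centroid
    w0 <- w0 - u * sum(w0 * u)
    if (vnorm(w0) < 1e-6) w0 <- vcross(u, c(0, 0, 1))
    w0 <- vunit(w0)
    cosa <- (d - 2.05) / (2 * 1.81)
    sina <- sqrt(max(0, 1 - cosa^2))
    # scan azimuthal orientations of the out-of-axis SG component so that
    # the closure solution also clears the backbone sterically
    for (az in deg2rad(c(0, 40, -40, 80, -80, 120, -120, 160, -160))) {
      w <- w0 * cos(az) + vcross(u, w0) * sin(az)
      sg1 <- cb1 + 1.81 * (cosa * u + sina * w)
      sgn <- cbn + 1.81 * (-cosa * u + sina * w)
      dss <- vnorm(sg1 - sgn)
      if (dss < 1.95 || dss > 2.15) next
      # SG pre-screen: clear of everything but its own CA (<= 2 bonds)
      if (min_to(sg1, !(bb_res == 1 & bb_atom == "CA")) < 2.25) next
      if (min_to(sgn, !(bb_res == n & bb_atom == "CA")) < 2.25) next
      if (vnorm(sg1 - cbn) < 2.25 || vnorm(sgn - cb1) < 2.25) next
      # last carbonyl: choose the psi whose implied C-terminal continuation
      # (the next N is placed anti to this O during growth, the next CA
      # trans to it) best clears the ring including the disulfide atoms
      obstacle <- rbind(bb_xyz[bb_res != n, , drop = FALSE], cb1, sg1, cbn, sgn)
      best_psi <- NA; best_clear <- -Inf
      for (psi_c in seq(-170, 170, by = 20)) {
        nn <- place_atom(coords[[n]]$N, coords[[n]]$CA, coords[[n]]$C,
                         g$b_c_n, g$a_ca_c_n, psi_c)
        can <- place_atom(coords[[n]]$CA, coords[[n]]$C, nn,
                          g$b_n_ca, g$a_c_n_ca, 180)
        clear <- min(sqrt(rowSums(sweep(obstacle, 2, nn)^2)),
                     sqrt(rowSums(sweep(obstacle, 2, can)^2)))
        if (clear > best_clear) { best_clear <- clear; best_psi <- psi_c }
      }
      if (best_clear < 3.0) next   # no unobstructed growth direction
      On <- place_atom(coords[[n]]$N, coords[[n]]$CA, coords[[n]]$C,
                       g$b_c_o, g$a_ca_c_o, best_psi + 180)
      if (is.null(base_rows)) {
        base_rows <- list()
        for (i in seq_len(n)) {
          for (nm in atoms_of(i))
            base_rows[[length(base_rows) + 1]] <- atom_row(i, nm, coords[[i]][[nm]])
        }
      }
      rows <- c(base_rows,
                list(atom_row(n, "O", On),
                     atom_row(1, "CB", cb1), atom_row(1, "SG", sg1),
                     atom_row(n, "CB", cbn), atom_row(n, "SG", sgn)))
      model <- new_model(paste(sequence3, collapse = ""), c(1, n),
                         do.call(rbind, rows))
      if (length(check_model(model)) == 0) return(model)
    }
  }
  NULL
}

# random interior sequence for a cyclic span (ends are always C)
cycle_sequence <- function(n) {
  c("C", sample(FIXTURE_AA, n - 2, replace = TRUE), "C")
}

#' Generate a synthetic disulfide-closed cyclic peptide structure
#'
#' Builds a geometrically valid cyclic span of `n_cyc` residues (terminal
#' cysteines bonded through SG-SG at ~2.05 Angstrom, complete backbones,
#' valid peptide bonds, no steric clashes) with optional non-cyclic tails
#' grown residue by residue.  The result passes every cyclic-fragment
#' extraction filter and yields exactly one fragment.
#'
#' @param n_cyc cyclic span length in \[3, 30\].
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param tail_lengths c(n_terminal, c_terminal) residue counts to grow
#'   outside the cyclic span.
#' @param resolution Angstrom recorded in the header; `NULL` draws one
#'   uniformly from \[1.0, 2.8\].
#' @param pdb_id identifier tag for the synthetic structure.
#' @param max_tries construction retries before giving up.
#' @return A `pep_structure`.
#' @export
make_ideal_cycle <- function(n_cyc, seed = NULL, tail_lengths = c(0, 0),
                             resolution = NULL, pdb_id = "SYN1",
                             max_tries = 50) {
  if (n_cyc < 3 || n_cyc > 30)
    cyc_error("cycpep_domain_error", "n_cyc must be in [3, 30]")
  if (!is.null(seed)) set.seed(seed)
  build_fixture_structure(n_cyc, tail_lengths, resolution, pdb_id, max_tries)
}

# internal variant without the public length cap (used for overlong defects)
build_fixture_structure <- function(n_cyc, tail_lengths, resolution, pdb_id,
                                    max_tries = 50) {
  if (is.null(resolution)) resolution <- round(stats::runif(1, 1.0, 2.8), 2)
  nt <- tail_lengths[1]; ct <- tail_lengths[2]
  rotamers <- if (nt + ct > 0) make_toy_rotamer_library() else NULL
  for (try in seq_len(max_tries)) {
    seq_cyc <- cycle_sequence(n_cyc)
    model <- build_cycle_once(n_cyc, seq_cyc)
    if (is.null(model)) next
    if (nt + ct > 0) {
      seq_full <- c(sample(FIXTURE_AA, nt, replace = TRUE), seq_cyc,
                    sample(FIXTURE_AA, ct, replace = TRUE))
      model$sequence <- paste(seq_full, collapse = "")
      model$atoms$res_index <- model$atoms$res_index + nt
      model$disulfide <- c(nt + 1, nt + n_cyc)
      ok <- TRUE
      if (nt > 0) for (p in nt:1) {
        model <- extend_residue(model, p, "N", rotamers)
        if (is.null(model)) { ok <- FALSE; break }
      }
      if (ok && ct > 0) for (p in (nt + n_cyc + 1):(nt + n_cyc + ct)) {
        model <- extend_residue(model, p, "C", rotamers)
        if (is.null(model)) { ok <- FALSE; break }
      }
      if (!ok) next
      if (length(check_model(model)) > 0) next
    }
    s <- model_as_structure(model)
    s$pdb_id <- pdb_id
    s$resolution <- resolution
    return(s)
  }
  stop("failed to construct a valid cyclic fixture of length ", n_cyc,
       " in ", max_tries, " tries")
}

#' Describe a synthetic fixture corpus
#'
#' @param n_structures number of PDB files to generate.
#' @param length_range c(min, max) cyclic-span lengths, within \[3, 30\];
#'   lengths cycle through this range across files.
#' @param tail_lengths c(n_terminal, c_terminal) residues outside the span.
#' @param defect_rate fraction of files receiving a disqualifying defect
#'   (extra interior cysteine, one deleted backbone O, or an overlong
#'   31-residue span).
#' @param seed integer seed; fully determines the corpus.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_structures, length_range = c(3, 30),
                         tail_lengths = c(0, 0), defect_rate = 0, seed = 1) {
  stopifnot(n_structures >= 1,
            length_range[1] >= 3, length_range[2] <= 30,
            length_range[1] <= length_range[2],
            defect_rate >= 0, defect_rate <= 1, all(tail_lengths >= 0))
  structure(list(n_structures = as.integer(n_structures),
                 length_range = as.integer(length_range),
                 tail_lengths = as.integer(tail_lengths),
                 defect_rate = defect_rate, seed = as.integer(seed)),
            class = "fixture_spec")
}

apply_defect <- function(s, defect) {
  if (defect == "extra_cys") {
    span <- s$ssbond[[1]]
    interior <- (span[1] + 1):(span[2] - 1)
    k <- interior[ceiling(length(interior) / 2)]
    s$residues$name[k] <- "CYS"   # no SG: disqualifies, cannot pair
  } else if (defect == "missing_o") {
    span <- s$ssbond[[1]]
    k <- span[1] + 1
    drop <- s$atoms$res_index == k & s$atoms$atom == "O"
    s$atoms <- s$atoms[!drop, , drop = FALSE]
  }
  s
}

#' Generate a synthetic fixture corpus on disk
#'
#' Writes `n_structures` PDB files plus `manifest.json` recording, per file,
#' the cyclic length, the injected defect (if any) and the ground-truth
#' number of qualifying cyclic fragments the extractor must find (1 for a
#' defect-free file, 0 for a defective one).
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return The manifest, invisibly (a list with one entry per file).
#' @export
make_fixture_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n <- spec$n_structures
  lens <- rep(seq(spec$length_range[1], spec$length_range[2]), length.out = n)
  n_defect <- round(spec$defect_rate * n)
  defect_files <- if (n_defect > 0) sample.int(n, n_defect) else integer(0)
  defect_types <- rep(c("extra_cys", "missing_o", "overlong"),
                      length.out = n_defect)
  manifest <- list()
  for (i in seq_len(n)) {
    defect <- "none"
    len <- lens[i]
    if (i %in% defect_files) {
      defect <- defect_types[match(i, defect_files)]
      if (defect == "overlong") len <- 31
    }
    pdb_id <- sprintf("S%03d", i)
    s <- build_fixture_structure(len, spec$tail_lengths, NULL, pdb_id)
    if (defect %in% c("extra_cys", "missing_o")) s <- apply_defect(s, defect)
    file <- sprintf("fixture_%03d.pdb", i)
    writeLines(write_structure(s), file.path(dir, file))
    manifest[[i]] <- list(file = file, pdb_id = pdb_id, length = len,
                          tail_lengths = spec$tail_lengths, defect = defect,
                          qualifying_fragments = if (defect == "none") 1L else 0L)
  }
  jsonlite::write_json(list(spec = unclass(spec), files = manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a fixture corpus directory as structures
#'
#' @param dir directory written by [make_fixture_corpus()].
#' @return List with `structures` (list of `pep_structure`) and `manifest`.
#' @export
read_fixture_corpus <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structures <- lapply(mf$files, function(e)
    parse_structure(readLines(file.path(dir, e$file)), chain_id = "A"))
  list(structures = structures, manifest = mf$files)
}
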