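# Full-atom conformer assembly: cyclic backbone from a sampled template,
# side chains from the rotamer library, non-cyclic termini grown residue by
# residue in internal coordinates, with steric and diversity filtering.
#
# A `pep_model` is a list with:
#   sequence  : full one-letter sequence
#   disulfide : c(i, j), 1-based positions of the bonded cysteines
#   atoms     : data.frame (res_index, atom, element, x, y, z)
#   provenance: list(template_source, template_index, seed)

CLASH_DIST <- 2.2  # heavy-atom pairs >= 3 bonds apart closer than this clash

#' Describe one modeling request
#'
#' @param sequence one-letter peptide sequence (length 3 to 40).
#' @param cys_positions ordered pair of 1-based positions of the two
#'   disulfide-bonded cysteines; both must be 'C' and the enclosed span must
#'   be 3 to 30 residues long.
#' @param n_models number of conformers requested.
#' @param seed integer seed making generation reproducible.
#' @param max_attempts_per_model attempt budget multiplier; generation stops
#'   after `n_models * max_attempts_per_model` construction attempts.
#' @return A `modeling_request` list.
#' @export
modeling_request <- function(sequence, cys_positions, n_models, seed = 1,
                             max_attempts_per_model = 100) {
  letters1 <- check_seq(sequence, "sequence")
  n <- length(letters1)
  if (n < 3 || n > 40) stop("sequence length must be in [3, 40]")
  cys_positions <- sort(as.integer(cys_positions))
  if (length(cys_positions) != 2 || any(is.na(cys_positions)) ||
      cys_positions[1] < 1 || cys_positions[2] > n)
    stop("cys_positions must be two valid 1-based positions")
  if (!all(letters1[cys_positions] == "C"))
    stop("both cys_positions must point at 'C' residues")
  n_cyc <- diff(cys_positions) + 1
  if (n_cyc < 3 || n_cyc > 30) stop("cyclic span length must be in [3, 30]")
  stopifnot(n_models >= 0, max_attempts_per_model >= 1)
  structure(list(sequence = toupper(sequence), cys_positions = cys_positions,
                 n_models = as.integer(n_models), seed = as.integer(seed),
                 max_attempts_per_model = as.integer(max_attempts_per_model)),
            class = "modeling_request")
}

new_model <- function(sequence, disulfide, atoms, provenance = list()) {
  structure(list(sequence = toupper(sequence), disulfide = disulfide,
                 atoms = atoms, provenance = provenance),
            class = "pep_model")
}

#' @export
print.pep_model <- function(x, ...) {
  cat(sprintf("<pep_model> %s (SS %d-%d), %d atoms\n", x$sequence,
              x$disulfide[1], x$disulfide[2], nrow(x$atoms)))
  invisible(x)
}

model_residue_names <- function(model) {
  aa_one_to_three(strsplit(model$sequence, "")[[1]])
}

model_as_structure <- function(model) {
  n <- nchar(model$sequence)
  res <- data.frame(res_index = seq_len(n), name = model_residue_names(model),
                    seq_id = seq_len(n), icode = "", is_standard = TRUE,
                    mapped_name = NA_character_, stringsAsFactors = FALSE)
  a <- model$atoms[order(model$atoms$res_index), , drop = FALSE]
  if (is.null(a$occupancy)) a$occupancy <- 1
  structure(list(pdb_id = "MODL", chain_id = "A", residues = res, atoms = a,
                 resolution = NA_real_, ssbond = list(model$disulfide)),
            class = "pep_structure")
}

# light-weight atom-table constructors (hot path: avoid data.frame() and
# rbind.data.frame overhead)
new_atom_df <- function(res_index, atom, x, y, z) {
  structure(list(res_index = res_index, atom = atom,
                 element = substr(gsub("[0-9]", "", atom), 1, 1),
                 x = x, y = y, z = z),
            class = "data.frame", row.names = seq_along(atom))
}

bind_atoms <- function(a, b) {
  if (is.null(b)) return(a)
  structure(list(res_index = c(a$res_index, b$res_index),
                 atom = c(a$atom, b$atom),
                 element = c(a$element, b$element),
                 x = c(a$x, b$x), y = c(a$y, b$y), z = c(a$z, b$z)),
            class = "data.frame",
            row.names = seq_len(length(a$atom) + length(b$atom)))
}

atom_row <- function(res_index, name, xyz) {
  new_atom_df(res_index, name, xyz[1], xyz[2], xyz[3])
}

sidechain_rows <- function(res_index, m) {
  if (is.null(m)) return(NULL)
  new_atom_df(rep(res_index, nrow(m)), rownames(m), m[, 1], m[, 2], m[, 3])
}

model_atom_coord <- function(model, res_index, name) {
  a <- model$atoms
  w <- which(a$res_index == res_index & a$atom == name)
  if (length(w) == 0) return(NULL)
  c(a$x[w[1]], a$y[w[1]], a$z[w[1]])
}

# Backbone coordinate matrix (rows N, CA, C, O per residue present, in
# residue order).  Residues must all have complete backbones.
model_backbone_matrix <- function(model) {
  a <- model$atoms[model$atoms$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  n_res <- length(unique(a$res_index))
  if (nrow(a) != 4 * n_res) stop("model has incomplete backbones")
  a <- a[order(a$res_index, match(a$atom, BACKBONE_ATOMS)), , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

# cached intra-residue bond-path lengths (atoms of one residue type)
respath_cache <- new.env(parent = emptyenv())

residue_path_matrix <- function(res_type) {
  res_type <- toupper(res_type)
  if (!is.null(respath_cache[[res_type]])) return(respath_cache[[res_type]])
  atoms <- c(BACKBONE_ATOMS, sidechain_atom_names(res_type))
  k <- length(atoms)
  adj <- matrix(FALSE, k, k, dimnames = list(atoms, atoms))
  for (b in residue_bonds(res_type)) {
    if (all(b %in% atoms)) adj[b[1], b[2]] <- adj[b[2], b[1]] <- TRUE
  }
  dm <- matrix(9L, k, k, dimnames = list(atoms, atoms))
  diag(dm) <- 0L
  reach <- diag(TRUE, k)
  step <- adj
  for (d in 1:3) {
    newly <- step & !reach & dm == 9L
    dm[newly] <- d
    reach <- reach | step
    step <- (step %*% adj) > 0
  }
  respath_cache[[res_type]] <- dm
  dm
}

# Incremental steric check: do the atoms of `new_rows` (all belonging to
# residue `res_idx`) clash with the current model?  A pair counts as a clash
# when it is at least three bonds apart and closer than the threshold;
# bond paths are computed from the per-residue-type path matrices plus the
# peptide links to the flanking residues.
steric_ok <- function(model, new_rows, res_idx, threshold = CLASH_DIST) {
  ex <- model$atoms
  if (nrow(ex) == 0) return(TRUE)
  xyz_e <- cbind(ex$x, ex$y, ex$z)
  xyz_n <- cbind(new_rows$x, new_rows$y, new_rows$z)
  d2 <- outer(rowSums(xyz_n^2), rowSums(xyz_e^2), "+") - 2 * xyz_n %*% t(xyz_e)
  near <- which(d2 < threshold^2, arr.ind = TRUE)
  if (nrow(near) == 0) return(TRUE)
  res3 <- model_residue_names(model)
  pm_new <- residue_path_matrix(res3[res_idx])
  for (r in seq_len(nrow(near))) {
    na <- new_rows$atom[near[r, 1]]
    ea <- ex$atom[near[r, 2]]
    er <- ex$res_index[near[r, 2]]
    path <- if (er == res_idx) {
      pm_new[na, ea]
    } else if (er == res_idx - 1) {
      pm_new[na, "N"] + 1L + residue_path_matrix(res3[er])["C", ea]
    } else if (er == res_idx + 1) {
      pm_new[na, "C"] + 1L + residue_path_matrix(res3[er])["N", ea]
    } else 9L
    if (path >= 3) return(FALSE)
  }
  TRUE
}

# --- bond graph and steric checking ---------------------------------------

# adjacency (logical) over the model's atoms, in atoms-table row order
model_adjacency <- function(model) {
  a <- model$atoms
  n <- nrow(a)
  key <- paste0(a$res_index, "|", a$atom)
  idx <- structure(seq_len(n), names = key)
  adj <- matrix(FALSE, n, n)
  res3 <- model_residue_names(model)
  for (i in sort(unique(a$res_index))) {
    for (b in residue_bonds(res3[i])) {
      k1 <- idx[paste0(i, "|", b[1])]
      k2 <- idx[paste0(i, "|", b[2])]
      if (!is.na(k1) && !is.na(k2)) adj[k1, k2] <- adj[k2, k1] <- TRUE
    }
    k1 <- idx[paste0(i, "|C")]
    k2 <- idx[paste0(i + 1, "|N")]
    if (!is.na(k1) && !is.na(k2)) adj[k1, k2] <- adj[k2, k1] <- TRUE
  }
  k1 <- idx[paste0(model$disulfide[1], "|SG")]
  k2 <- idx[paste0(model$disulfide[2], "|SG")]
  if (!is.na(k1) && !is.na(k2)) adj[k1, k2] <- adj[k2, k1] <- TRUE
  adj
}

# Pairs of atoms separated by >= 3 bonds that lie closer than `threshold`.
model_clashes <- function(model, threshold = CLASH_DIST) {
  a <- model$atoms
  n <- nrow(a)
  if (n < 2) return(data.frame())
  adj <- model_adjacency(model)
  near <- adj | (adj %*% adj > 0)  # path length <= 2
  diag(near) <- TRUE
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))
  hit <- which(d2 < threshold & !near, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (nrow(hit) == 0) return(data.frame())
  data.frame(i = hit[, 1], j = hit[, 2],
             atom_i = paste0(a$res_index[hit[, 1]], ":", a$atom[hit[, 1]]),
             atom_j = paste0(a$res_index[hit[, 2]], ":", a$atom[hit[, 2]]),
             dist = d2[hit])
}

#' Check the structural invariants of a model
#'
#' Verifies that consecutive peptide C-N bonds lie in \[1.23, 1.43\] Angstrom,
#' the disulfide SG-SG distance lies in \[1.8, 2.5\] Angstrom, and no
#' heavy-atom pair separated by at least three bonds is closer than the clash
#' threshold (2.2 Angstrom).
#'
#' @param model a `pep_model`.
#' @param clash_threshold Angstrom.
#' @return Character vector of violation descriptions; empty when the model
#'   is valid.
#' @export
check_model <- function(model, clash_threshold = CLASH_DIST) {
  problems <- character(0)
  n <- nchar(model$sequence)
  for (i in seq_len(n - 1)) {
    ci <- model_atom_coord(model, i, "C")
    ni <- model_atom_coord(model, i + 1, "N")
    if (is.null(ci) || is.null(ni)) {
      problems <- c(problems, sprintf("missing backbone at junction %d-%d", i, i + 1))
      next
    }
    d <- vnorm(ci - ni)
    if (d < 1.23 || d > 1.43)
      problems <- c(problems, sprintf("peptide bond %d-%d length %.3f A", i, i + 1, d))
  }
  sg1 <- model_atom_coord(model, model$disulfide[1], "SG")
  sg2 <- model_atom_coord(model, model$disulfide[2], "SG")
  if (is.null(sg1) || is.null(sg2)) {
    problems <- c(problems, "missing SG atom on a disulfide cysteine")
  } else {
    d <- vnorm(sg1 - sg2)
    if (d < 1.8 || d > 2.5)
      problems <- c(problems, sprintf("SG-SG distance %.3f A", d))
  }
  cl <- model_clashes(model, clash_threshold)
  if (nrow(cl) > 0)
    problems <- c(problems, sprintf("%d steric clash(es), closest %s-%s %.2f A",
                                    nrow(cl), cl$atom_i[1], cl$atom_j[1],
                                    min(cl$dist)))
  problems
}

# --- cyclic part -----------------------------------------------------------

#' Build the cyclic part of a model from a backbone template
#'
#' Backbone coordinates are copied verbatim from the template, the terminal
#' cysteines keep the template's side-chain atoms (CB, SG), and every
#' interior residue receives a frequency-weighted rotamer draw mapped through
#' its local backbone frame.  Glycine gets no side chain.  Rotamers clashing
#' with already-placed atoms are redrawn up to `max_redraw` times.
#'
#' @param template a `cyclic_fragment`.
#' @param target_cyclic_seq one-letter sequence of the cyclic span (same
#'   length as the template; both ends 'C').
#' @param rotamers a `rotamer_library`.
#' @param offset 1-based position of the cyclic span's first residue in the
#'   full sequence.
#' @param max_redraw rotamer redraws allowed per residue on steric clash.
#' @return A partial `pep_model` covering the cyclic span, or `NULL` when a
#'   clash could not be resolved.
#' @export
build_cyclic_part <- function(template, target_cyclic_seq, rotamers,
                              offset = 1, max_redraw = 20) {
  letters1 <- check_seq(target_cyclic_seq, "target_cyclic_seq")
  n <- template$length
  if (length(letters1) != n)
    cyc_error("cycpep_domain_error",
              "target cyclic sequence length does not match template length")
  if (letters1[1] != "C" || letters1[n] != "C")
    cyc_error("cycpep_domain_error", "cyclic span endpoints must be 'C'")
  span <- offset:(offset + n - 1)
  rows <- list()
  for (k in seq_len(n)) {
    bb <- template$bb[(4 * (k - 1) + 1):(4 * k), , drop = FALSE]
    rownames(bb) <- BACKBONE_ATOMS
    rows[[length(rows) + 1]] <- sidechain_rows(span[k], bb)
  }
  rows[[length(rows) + 1]] <- sidechain_rows(span[1], template$cys_first)
  rows[[length(rows) + 1]] <- sidechain_rows(span[n], template$cys_last)
  seq_full <- paste(letters1, collapse = "")
  model <- new_model(seq_full, c(span[1], span[n]) - offset + 1,
                     Reduce(bind_atoms, rows))
  # positions are span-local while building; re-indexed by the caller
  model$atoms$res_index <- model$atoms$res_index - offset + 1

  for (k in 2:(n - 1)) {
    res1 <- letters1[k]
    if (res1 == "G") next
    res3 <- aa_one_to_three(res1)
    Nk <- model_atom_coord(model, k, "N")
    CAk <- model_atom_coord(model, k, "CA")
    Ck <- model_atom_coord(model, k, "C")
    placed <- FALSE
    for (try in seq_len(max_redraw)) {
      rot <- draw_rotamer(rotamers, res3)
      sc <- apply_rotamer(rot$atoms, Nk, CAk, Ck)
      rows <- sidechain_rows(k, sc)
      if (steric_ok(model, rows, k)) {
        model$atoms <- bind_atoms(model$atoms, rows)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  model
}

# --- terminus growth -------------------------------------------------------

#' Grow one residue onto a chain terminus
#'
#' Draws backbone dihedrals (phi, psi, omega) from the rotamer library's
#' per-residue table (with a small Gaussian jitter), places the new backbone
#' with ideal bond lengths and angles by natural-extension construction,
#' places the side chain from a rotamer draw, and redraws on steric clash.
#'
#' @param model a partial `pep_model` whose atoms use full-sequence
#'   `res_index` positions.
#' @param position 1-based position of the residue to add; must extend the
#'   current span by one on the requested side.
#' @param direction `"N"` (prepend) or `"C"` (append).
#' @param rotamers a `rotamer_library`.
#' @param max_redraw redraw budget on steric clash.
#' @return The extended model (with attribute `"dihedrals"` holding the drawn
#'   phi/psi/omega), or `NULL` when every redraw clashed.
#' @export
extend_residue <- function(model, position, direction = c("C", "N"),
                           rotamers, max_redraw = 20) {
  direction <- direction[1]
  if (!direction %in% c("C", "N")) stop("direction must be 'C' or 'N'")
  res3 <- model_residue_names(model)[position]
  have <- range(model$atoms$res_index)
  if (direction == "C" && position != have[2] + 1)
    stop("C-terminal growth must extend the span by one")
  if (direction == "N" && position != have[1] - 1)
    stop("N-terminal growth must extend the span by one")
  j <- if (direction == "C") position - 1 else position + 1
  Nj <- model_atom_coord(model, j, "N")
  CAj <- model_atom_coord(model, j, "CA")
  Cj <- model_atom_coord(model, j, "C")
  Oj <- model_atom_coord(model, j, "O")
  if (is.null(Nj) || is.null(CAj) || is.null(Cj) || is.null(Oj))
    stop("junction residue lacks backbone atoms")
  g <- IDEAL_GEOM
  for (try in seq_len(max_redraw)) {
    dih <- draw_backbone_dihedrals(rotamers, res3)
    if (direction == "C") {
      # previous psi is implied by the existing carbonyl oxygen
      psi_prev <- dihedral(Nj, CAj, Cj, Oj) + 180
      Nn <- place_atom(Nj, CAj, Cj, g$b_c_n, g$a_ca_c_n, psi_prev)
      CAn <- place_atom(CAj, Cj, Nn, g$b_n_ca, g$a_c_n_ca, dih["omega"])
      Cn <- place_atom(Cj, Nn, CAn, g$b_ca_c, g$a_n_ca_c, dih["phi"])
      On <- place_atom(Nn, CAn, Cn, g$b_c_o, g$a_ca_c_o, dih["psi"] + 180)
    } else {
      Cn <- place_atom(Cj, CAj, Nj, g$b_c_n, g$a_c_n_ca, dih["phi"])
      CAn <- place_atom(CAj, Nj, Cn, g$b_ca_c, g$a_ca_c_n, dih["omega"])
      Nn <- place_atom(Nj, Cn, CAn, g$b_n_ca, g$a_n_ca_c, dih["psi"])
      On <- place_atom(Nn, CAn, Cn, g$b_c_o, g$a_ca_c_o, dih["psi"] + 180)
    }
    bb <- rbind(N = Nn, CA = CAn, C = Cn, O = On)
    sc <- NULL
    if (res3 != "GLY") {
      rot <- draw_rotamer(rotamers, res3)
      sc <- apply_rotamer(rot$atoms, Nn, CAn, Cn)
    }
    rows <- sidechain_rows(position, bb)
    if (!is.null(sc)) rows <- bind_atoms(rows, sidechain_rows(position, sc))
    if (steric_ok(model, rows, position)) {
      cand <- model
      cand$atoms <- bind_atoms(model$atoms, rows)
      attr(cand, "dihedrals") <- dih
      return(cand)
    }
  }
  NULL
}

# --- diversity filter ------------------------------------------------------

#' Ensemble diversity filter
#'
#' A candidate is accepted iff its optimally-superposed backbone RMSD to
#' every previously accepted model is at least `cutoff` (1.0 Angstrom by
#' default); a candidate within less than the cutoff of any accepted model is
#' discarded.  An empty accepted set always accepts.
#'
#' @param candidate a `pep_model`.
#' @param accepted list of `pep_model`s of the same sequence length.
#' @param cutoff Angstrom.
#' @return Logical flag.
#' @export
diversity_accept <- function(candidate, accepted, cutoff = 1.0) {
  if (length(accepted) == 0) return(TRUE)
  cb <- model_backbone_matrix(candidate)
  for (m in accepted) {
    if (superposed_rmsd(model_backbone_matrix(m), cb) < cutoff) return(FALSE)
  }
  TRUE
}

# --- ensemble generation ---------------------------------------------------

#' Generate a conformer ensemble for a disulfide-cyclized peptide
#'
#' Repeats: sample a backbone template from the length-matched sub-library
#' with probability proportional to
#' `exp(w_s * s_i / s_max + w_r * r_i / r_max)`, copy its backbone and
#' terminal-cysteine side chains, build interior side chains from rotamers,
#' grow the N-terminal tail (residue by residue, in reverse) then the
#' C-terminal tail, and keep the model if it passes the structural invariants
#' and the 1.0-Angstrom ensemble diversity filter -- until `n_models` models
#' are accepted or the attempt budget
#' (`n_models * max_attempts_per_model`) is exhausted (then a shortfall
#' warning is issued).  Fully reproducible for a fixed request seed.
#'
#' @param request a [modeling_request()].
#' @param library a `backbone_library` with a sub-library for the request's
#'   cyclic length.
#' @param rotamers a `rotamer_library`; defaults to the built-in toy library.
#' @param weights a [selection_weights()].
#' @param diversity_cutoff Angstrom; minimum pairwise backbone RMSD.
#' @param identity_cutoff optional percent-identity cutoff; templates at
#'   least this identical to the target cyclic sequence are removed before
#'   sampling.
#' @return A `pep_ensemble`: list with `request`, `models` (ordered as
#'   accepted), `n_attempts`.
#' @export
generate_ensemble <- function(request, library, rotamers = make_toy_rotamer_library(),
                              weights = selection_weights(),
                              diversity_cutoff = 1.0, identity_cutoff = NULL) {
  stopifnot(inherits(request, "modeling_request"))
  i <- request$cys_positions[1]
  j <- request$cys_positions[2]
  n <- nchar(request$sequence)
  cyc_seq <- substr(request$sequence, i, j)
  templates <- sub_library(library, nchar(cyc_seq))
  if (length(templates) == 0)
    cyc_error("cycpep_no_template",
              paste0("library has no sub-library for cyclic length ", nchar(cyc_seq)))
  if (!is.null(identity_cutoff))
    templates <- filter_by_identity(templates, cyc_seq, identity_cutoff)
  scores <- template_probabilities(templates, cyc_seq, weights)

  set.seed(request$seed)
  accepted <- list()
  accepted_bbs <- list()
  budget <- request$n_models * request$max_attempts_per_model
  attempts <- 0
  while (length(accepted) < request$n_models && attempts < budget) {
    attempts <- attempts + 1
    ti <- sample_template(scores)
    model <- build_cyclic_part(templates[[ti]], cyc_seq, rotamers, offset = 1)
    if (is.null(model)) next
    # re-index the cyclic part into full-sequence positions
    model$atoms$res_index <- model$atoms$res_index + i - 1
    model$sequence <- request$sequence
    model$disulfide <- c(i, j)
    ok <- TRUE
    if (i > 1) for (p in (i - 1):1) {
      model <- extend_residue(model, p, "N", rotamers)
      if (is.null(model)) { ok <- FALSE; break }
    }
    if (ok && j < n) for (p in (j + 1):n) {
      model <- extend_residue(model, p, "C", rotamers)
      if (is.null(model)) { ok <- FALSE; break }
    }
    if (!ok) next
    if (length(check_model(model)) > 0) next
    cand_bb <- model_backbone_matrix(model)
    diverse <- TRUE
    for (bb in accepted_bbs) {
      if (superposed_rmsd(bb, cand_bb) < diversity_cutoff) { diverse <- FALSE; break }
    }
    if (!diverse) next
    accepted_bbs[[length(accepted_bbs) + 1]] <- cand_bb
    model$atoms <- model$atoms[order(model$atoms$res_index), , drop = FALSE]
    model$provenance <- list(
      template_index = ti,
      template_source = paste0(templates[[ti]]$source_pdb, "_",
                               templates[[ti]]$source_chain),
      attempt = attempts, seed = request$seed)
    accepted[[length(accepted) + 1]] <- model
  }
  if (length(accepted) < request$n_models)
    warning(sprintf("generated %d of %d requested models within the attempt budget",
                    length(accepted), request$n_models))
  structure(list(request = request, models = accepted, n_attempts = attempts),
            class = "pep_ensemble")
}

#' @export
print.pep_ensemble <- function(x, ...) {
  cat(sprintf("<pep_ensemble> %s: %d models (%d attempts)\n",
              x$request$sequence, length(x$models), x$n_attempts))
  invisible(x)
}

#' Write an ensemble to PDB files
#'
#' Either one file per model (`model_0001.pdb`, ...) or a single multi-MODEL
#' file `ensemble.pdb`.
#'
#' @param ensemble a `pep_ensemble`.
#' @param dir output directory.
#' @param multi_model write one multi-MODEL file instead of one file per
#'   model.
#' @return Invisibly, the written file paths.
#' @export
write_ensemble <- function(ensemble, dir, multi_model = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (multi_model) {
    out <- character(0)
    for (k in seq_along(ensemble$models)) {
      body <- write_structure(ensemble$models[[k]])
      body <- body[!body %in% "END"]
      out <- c(out, sprintf("MODEL     %4d", k), body, "ENDMDL")
    }
    f <- file.path(dir, "ensemble.pdb")
    writeLines(c(out, "END"), f)
    return(invisible(f))
  }
  files <- vapply(seq_along(ensemble$models), function(k) {
    f <- file.path(dir, sprintf("model_%04d.pdb", k))
    writeLines(write_structure(ensemble$models[[k]]), f)
    f
  }, character(1))
  invisible(files)
}
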