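# Rotamer library: side-chain conformers stored in a local backbone frame
# (origin CA, axes derived from N/CA/C) plus per-residue backbone
# (phi, psi, omega) tables used for residue-by-residue terminus growth.

# orthonormal local frame rows (ex, ey, ez) from backbone N, CA, C
local_frame <- function(N, CA, C) {
  ex <- vunit(N - CA)
  v <- C - CA
  ez <- vunit(vcross(ex, v))
  ey <- vcross(ez, ex)
  rbind(ex, ey, ez)
}

# canonical backbone triad whose local frame is the identity
canonical_backbone <- function() {
  th <- deg2rad(IDEAL_GEOM$a_n_ca_c)
  list(N = c(IDEAL_GEOM$b_n_ca, 0, 0),
       CA = c(0, 0, 0),
       C = IDEAL_GEOM$b_ca_c * c(cos(th), sin(th), 0))
}

# Build side-chain heavy atoms for `res_type` with torsions `chis`, given
# actual backbone coordinates.  Returns a named matrix (rows = atom names).
build_sidechain <- function(res_type, chis, N, CA, C) {
  res_type <- toupper(res_type)
  if (res_type == "GLY") return(NULL)
  pos <- list(N = N, CA = CA, C = C)
  pos$CB <- place_atom(pos$N, pos$C, pos$CA, 1.53, 110.1, -122.6)  # L chirality
  zm <- sidechain_zmat[[res_type]]
  if (!is.null(zm)) {
    for (i in seq_len(nrow(zm))) {
      tor <- if (zm$tref[i] > 0) chis[zm$tref[i]] + zm$toff[i] else zm$toff[i]
      pos[[zm$atom[i]]] <- place_atom(pos[[zm$a[i]]], pos[[zm$b[i]]],
                                      pos[[zm$c[i]]], zm$bond[i],
                                      zm$angle[i], tor)
    }
  }
  nm <- setdiff(names(pos), c("N", "CA", "C"))
  m <- do.call(rbind, pos[nm])
  rownames(m) <- nm
  m
}

#' Minimal built-in rotamer library
#'
#' A deterministic stand-in library sufficient to build full-atom models:
#' every standard residue type gets side-chain conformers built from
#' idealized internal coordinates at the common chi1 staggered positions
#' (-60, 180, 60; proline uses its ring-compatible pucker), with uniform
#' frequencies, plus a backbone (phi, psi, omega) table covering the
#' alpha-helical, beta-strand and polyproline-II basins (glycine gains the
#' mirrored left-handed helix basin, proline is restricted to phi near -65).
#' All omega samples are trans.  [read_rotamer_library()] accepts
#' user-supplied replacements in the same plain-text layout.
#'
#' @return A `rotamer_library`: list with `side_chains` (per residue type, a
#'   list of conformers, each `list(atoms, weight)` with local-frame
#'   coordinates) and `backbone` (data.frame res, phi, psi, omega, weight).
#' @export
make_toy_rotamer_library <- function() {
  canon <- canonical_backbone()
  side <- list()
  for (res in AA3) {
    if (res == "GLY") {
      side[[res]] <- list(list(atoms = NULL, weight = 1))
      next
    }
    # proline chi1/chi2 are fixed by ring closure in this idealized geometry
    chi1s <- if (res == "ALA") 0 else if (res == "PRO") -12 else c(-60, 180, 60)
    tail <- DEFAULT_CHI_TAIL[[res]]
    confs <- lapply(chi1s, function(c1) {
      m <- build_sidechain(res, c(c1, tail), canon$N, canon$CA, canon$C)
      list(atoms = m, weight = 1 / length(chi1s))
    })
    side[[res]] <- confs
  }
  bb_rows <- list()
  # coil-like coverage of the allowed Ramachandran regions: helix, strand,
  # polyproline-II, extended, bridge and the sparser left-handed-helix basin
  basins <- data.frame(
    phi = c(-63, -120, -75, -155, -95, 57),
    psi = c(-43, 130, 145, 155, 5, 47),
    omega = 180,
    weight = c(0.28, 0.22, 0.2, 0.12, 0.08, 0.10))
  for (res in AA3) {
    b <- basins
    if (res == "GLY")
      b <- data.frame(phi = c(-63, -120, -75, -155, 63, 85, 80),
                      psi = c(-43, 130, 145, 155, 43, -5, 170),
                      omega = 180,
                      weight = c(0.2, 0.15, 0.15, 0.1, 0.15, 0.1, 0.15))
    if (res == "PRO")
      b <- data.frame(phi = c(-65, -65, -65), psi = c(145, -35, 170),
                      omega = 180, weight = c(0.5, 0.3, 0.2))
    b$res <- res
    bb_rows[[res]] <- b
  }
  structure(list(side_chains = side,
                 backbone = do.call(rbind, c(bb_rows, make.row.names = FALSE))),
            class = "rotamer_library")
}

validate_rotamer_library <- function(lib) {
  stopifnot(inherits(lib, "rotamer_library"))
  for (res in AA3) {
    confs <- lib$side_chains[[res]]
    if (is.null(confs) || length(confs) < 1)
      stop("rotamer library lacks side-chain conformers for ", res)
    want <- sidechain_atom_names(res)
    for (cf in confs) {
      have <- if (is.null(cf$atoms)) character(0) else rownames(cf$atoms)
      if (!setequal(have, want))
        stop("wrong heavy-atom composition for ", res)
    }
    if (sum(lib$backbone$res == res) < 1)
      stop("rotamer library lacks backbone samples for ", res)
  }
  invisible(TRUE)
}

# draw a side-chain conformer index for res_type (frequency-weighted)
draw_rotamer <- function(lib, res_type) {
  confs <- lib$side_chains[[toupper(res_type)]]
  w <- vapply(confs, function(cf) cf$weight, numeric(1))
  confs[[sample.int(length(confs), 1, prob = w)]]
}

# draw a (phi, psi, omega) row for res_type with jitter (degrees, sd)
draw_backbone_dihedrals <- function(lib, res_type, jitter_sd = 14) {
  b <- lib$backbone[lib$backbone$res == toupper(res_type), , drop = FALSE]
  i <- sample.int(nrow(b), 1, prob = b$weight)
  c(phi = b$phi[i] + stats::rnorm(1, 0, jitter_sd),
    psi = b$psi[i] + stats::rnorm(1, 0, jitter_sd),
    omega = b$omega[i] + stats::rnorm(1, 0, 3))
}

# map local-frame side-chain coordinates onto an actual backbone
apply_rotamer <- function(atoms_local, N, CA, C) {
  if (is.null(atoms_local)) return(NULL)
  B <- local_frame(N, CA, C)
  m <- atoms_local %*% B          # rows are local coords; B rows are axes
  sweep(m, 2, CA, "+")
}

#' Write / read a rotamer library as plain text
#'
#' Layout: `sidechains.tsv` (columns res, conformer, weight, atom, x, y, z;
#' coordinates in the local backbone frame) and `backbone.tsv` (columns res,
#' phi, psi, omega, weight) inside `path`.
#'
#' @param lib a `rotamer_library`.
#' @param path directory.
#' @return `write_rotamer_library` returns `path` invisibly;
#'   `read_rotamer_library` returns a validated `rotamer_library`.
#' @export
write_rotamer_library <- function(lib, path) {
  validate_rotamer_library(lib)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (res in names(lib$side_chains)) {
    confs <- lib$side_chains[[res]]
    for (k in seq_along(confs)) {
      m <- confs[[k]]$atoms
      if (is.null(m)) {
        rows[[length(rows) + 1]] <- data.frame(
          res = res, conformer = k, weight = confs[[k]]$weight,
          atom = NA_character_, x = NA, y = NA, z = NA)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          res = res, conformer = k, weight = confs[[k]]$weight,
          atom = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
      }
    }
  }
  utils::write.table(do.call(rbind, rows), file.path(path, "sidechains.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(lib$backbone, file.path(path, "backbone.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rotamer_library
#' @export
read_rotamer_library <- function(path) {
  sc <- utils::read.table(file.path(path, "sidechains.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  bb <- utils::read.table(file.path(path, "backbone.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  side <- list()
  for (res in unique(sc$res)) {
    sub <- sc[sc$res == res, , drop = FALSE]
    side[[res]] <- lapply(sort(unique(sub$conformer)), function(k) {
      rows <- sub[sub$conformer == k, , drop = FALSE]
      if (all(is.na(rows$atom))) return(list(atoms = NULL, weight = rows$weight[1]))
      m <- unname(as.matrix(rows[, c("x", "y", "z")]))
      rownames(m) <- rows$atom
      list(atoms = m, weight = rows$weight[1])
    })
  }
  lib <- structure(list(side_chains = side, backbone = bb),
                   class = "rotamer_library")
  validate_rotamer_library(lib)
  lib
}
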